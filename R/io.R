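# Structure file I/O: PDB (CRYST1 + ATOM/HETATM + segid convention) and XYZ
# with a "box=a b c" comment record.
#
# Conventions (documented in README for bit-exact re-reading):
#   * chainID column (22) carries the polymer class letter:
#       C cellulose, X xylan, L lignin, W water, I ion, U unknown
#   * segid (73-76) is the class letter + zero-padded chain number (<= 999)
#   * resSeq is the 1-based residue_index, resName the residue type
#     (GLCA -> "GCA", WAT -> "HOH" on disk)
#   * atom serials above 99999 wrap; readers renumber sequentially.

CLASS_LETTER <- c(cellulose = "C", xylan = "X", lignin = "L",
                  water = "W", ion = "I", unknown = "U")
RES_TO_PDB <- c(GLC = "GLC", XYL = "XYL", GLCA = "GCA", ACE = "ACE",
                SYR = "SYR", GUA = "GUA", WAT = "HOH", "NA" = "NA")

#' Read a structure from PDB or XYZ
#'
#' The box is taken from the CRYST1 record (PDB) or a `box=a b c` token in
#' the comment line (XYZ); absent a box the structure is non-periodic and
#' periodic analyses will refuse it downstream.
#'
#' @param path file path.
#' @param format "pdb" or "xyz"; guessed from the extension when missing.
#' @param multi if TRUE and the PDB has MODEL records, return an
#'   `scw_trajectory` (list of structures); otherwise the first model.
#' @return an `scw_structure` (or `scw_trajectory` when `multi = TRUE`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           multi = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") read_pdb(path, multi = multi) else read_xyz(path)
}

read_pdb <- function(path, multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  box <- NULL
  cry <- grep("^CRYST1", lines)
  if (length(cry)) {
    l <- lines[cry[1]]
    box <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33))))
    if (anyNA(box))
      stop(sprintf("malformed CRYST1 record at line %d of %s", cry[1], path))
  }
  model_starts <- grep("^MODEL", lines)
  parse_block <- function(ln, off) {
    rec <- grepl("^(ATOM  |HETATM)", ln)
    idx <- which(rec)
    ln <- ln[rec]
    if (!length(ln))
      return(atom_table(character(), character(), integer(), character(),
                        integer(), numeric(), numeric(), numeric()))
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop(sprintf("malformed coordinate record at line %d of %s",
                   off + idx[bad[1]], path))
    name <- trimws(substr(ln, 13, 16))
    resname <- trimws(substr(ln, 18, 20))
    restype <- names(RES_TO_PDB)[match(resname, RES_TO_PDB)]
    restype[is.na(restype)] <- resname[is.na(restype)]
    resseq <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    if (anyNA(resseq))
      stop(sprintf("malformed residue number at line %d of %s",
                   off + idx[which(is.na(resseq))[1]], path))
    segid <- trimws(substr(ln, 73, 76))
    classletter <- substr(segid, 1, 1)
    pclass <- names(CLASS_LETTER)[match(classletter, CLASS_LETTER)]
    chain_no <- suppressWarnings(as.integer(substr(segid, 2, 4)))
    # fall back to the chainID column when segids are absent
    fallback <- is.na(pclass)
    if (any(fallback)) {
      cid <- substr(ln, 22, 22)
      pclass[fallback] <- names(CLASS_LETTER)[match(cid[fallback], CLASS_LETTER)]
      pclass[is.na(pclass)] <- "unknown"
      chain_no[is.na(chain_no)] <- 1L
    }
    elem <- trimws(substr(ln, 77, 78))
    elem[elem == ""] <- substr(name[elem == ""], 1, 1)
    atom_table(elem, name, resseq, restype, chain_no, x, y, z,
               polymer_class = pclass)
  }
  mk <- function(atoms) scw_structure(atoms, box = box,
                                      periodic = !is.null(box))
  if (length(model_starts) && multi) {
    ends <- grep("^ENDMDL", lines)
    frames <- lapply(seq_along(model_starts), function(i) {
      a <- model_starts[i]; b <- if (i <= length(ends)) ends[i] else length(lines)
      mk(parse_block(lines[a:b], a - 1L))
    })
    return(structure(frames, class = "scw_trajectory"))
  }
  if (length(model_starts)) {
    a <- model_starts[1]
    b <- if (length(grep("^ENDMDL", lines))) grep("^ENDMDL", lines)[1]
         else length(lines)
    return(mk(parse_block(lines[a:b], a - 1L)))
  }
  mk(parse_block(lines, 0L))
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop(sprintf("truncated XYZ file %s", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop(sprintf("malformed atom count at line 1 of %s", path))
  box <- NULL
  m <- regmatches(lines[2], regexec(
    "box=\\s*([0-9.eE+-]+)[ ,]+([0-9.eE+-]+)[ ,]+([0-9.eE+-]+)", lines[2]))[[1]]
  if (length(m) == 4) box <- as.numeric(m[2:4])
  if (n == 0)
    return(scw_structure(box = box, periodic = !is.null(box)))
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad))
    stop(sprintf("malformed XYZ record at line %d of %s", 2 + bad[1], path))
  elem <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                  numeric(3)))
  if (anyNA(xyz))
    stop(sprintf("non-numeric coordinates near line %d of %s",
                 2 + which(apply(is.na(xyz), 1, any))[1], path))
  atoms <- atom_table(elem, elem, 1L, "UNK", 1L, xyz[, 1], xyz[, 2], xyz[, 3],
                      polymer_class = "unknown")
  scw_structure(atoms, box = box, periodic = !is.null(box))
}

#' Write a structure to PDB or XYZ
#'
#' @param s an `scw_structure` or `scw_trajectory` (multi-model PDB).
#' @param path output path.
#' @param format "pdb" or "xyz"; guessed from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") write_pdb(s, path) else write_xyz(s, path)
  invisible(path)
}

pdb_atom_lines <- function(a) {
  if (nrow(a) == 0) return(character())
  serial <- (a$atom_id %% 99999L) + 1L
  name <- ifelse(nchar(a$atom_label) < 4, paste0(" ", a$atom_label),
                 a$atom_label)
  resname <- RES_TO_PDB[a$residue_type]
  resname[is.na(resname)] <- substr(a$residue_type[is.na(resname)], 1, 3)
  letter <- CLASS_LETTER[a$polymer_class]
  segid <- sprintf("%s%03d", letter, a$chain_id %% 1000L)
  elem <- toupper(a$element)
  # standard columns: name 13-16, resName 18-20, chainID 22, resSeq 23-26,
  # coords 31-54, segid 73-76, element 77-78
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          serial, name, resname, letter, a$residue_index %% 10000L,
          a$x, a$y, a$z, 1, 0, segid, elem)
}

write_pdb <- function(s, path) {
  frames <- if (inherits(s, "scw_trajectory")) s else list(s)
  out <- character()
  s1 <- frames[[1]]
  if (s1$periodic)
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                          s1$box[1], s1$box[2], s1$box[3], 90, 90, 90))
  if (length(frames) > 1) {
    for (i in seq_along(frames))
      out <- c(out, sprintf("MODEL %8d", i),
               pdb_atom_lines(frames[[i]]$atoms), "ENDMDL")
  } else {
    out <- c(out, pdb_atom_lines(s1$atoms))
  }
  writeLines(c(out, "END"), path)
}

write_xyz <- function(s, path) {
  if (inherits(s, "scw_trajectory")) s <- s[[1]]
  a <- s$atoms
  comment <- "scwforge"
  if (s$periodic)
    comment <- sprintf("scwforge box=%.6f %.6f %.6f",
                       s$box[1], s$box[2], s$box[3])
  body <- if (nrow(a)) sprintf("%-2s %12.6f %12.6f %12.6f",
                               a$element, a$x, a$y, a$z) else character()
  writeLines(c(as.character(nrow(a)), comment, body), path)
}
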