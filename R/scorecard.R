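# Model-vs-NMR scorecard: rank packing scenarios by how closely their
# proximity profiles match the four experimental magnetization metrics.

#' Score and rank models against the ssNMR proximity references
#'
#' Each model's four-metric [proximity_profile()] is compared to the
#' experimental reference percentages; the aggregate mismatch is the mean
#' of the four absolute deviations. Models are ranked by aggregate
#' mismatch, ties broken by the lignin->cellulose mismatch (the most
#' diagnostic metric for misplaced lignin), then by input order.
#'
#' @param models named list of periodic `scw_structure` objects (or file
#'   paths readable by [read_structure()]).
#' @param references reference percentages in canonical metric order
#'   (xylan->lignin, xylan->cellulose, lignin->xylan, lignin->cellulose).
#' @param cutoff proximity cutoff, Angstrom.
#' @return a `scw_scorecard` data.frame: one row per model with the four
#'   percentages, per-metric absolute mismatches, `aggregate` and `rank`.
#' @export
scorecard <- function(models, references = PROXIMITY_REFERENCES,
                      cutoff = PROXIMITY_CUTOFF) {
  if (inherits(models, "scw_structure")) models <- list(models)
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (is.character(m)) m <- read_structure(m)
    pr <- proximity_profile(m, cutoff = cutoff, references = references)
    mis <- abs(pr$percent - pr$reference)
    data.frame(model = nm[i],
               xylan_to_lignin = pr$percent[1],
               xylan_to_cellulose = pr$percent[2],
               lignin_to_xylan = pr$percent[3],
               lignin_to_cellulose = pr$percent[4],
               mismatch_xl = mis[1], mismatch_xc = mis[2],
               mismatch_lx = mis[3], mismatch_lc = mis[4],
               aggregate = mean(mis),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$aggregate, out$mismatch_lc, seq_len(nrow(out)))
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "references") <- references
  attr(out, "cutoff") <- cutoff
  class(out) <- c("scw_scorecard", "data.frame")
  out
}

#' @export
print.scw_scorecard <- function(x, ...) {
  cat(sprintf("<scorecard> cutoff %.1f A, references %s\n",
              attr(x, "cutoff"),
              paste(attr(x, "references"), collapse = "/")))
  print.data.frame(x[order(x$rank),
                     c("model", "xylan_to_lignin", "xylan_to_cellulose",
                       "lignin_to_xylan", "lignin_to_cellulose",
                       "aggregate", "rank")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}
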