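#' Contribution Fractions of signature probes for one treatment set
#'
#' For signature probe k the Contribution Fraction is
#' `CF_k = 1 - median(c*_k) / median(c)`, where `c` are the member instances'
#' connection scores, `c*_k` their diminished scores with probe k withheld
#' ([diminished_score()]), and the medians are taken over the set's instances
#' independently for the full and diminished scores. CF_k measures how much
#' of the set's connection the probe carries; probes opposing the connection
#' get negative CF.
#'
#' @param db a `ref_db`.
#' @param members instance ids of the treatment set.
#' @param sig a reconciled `query_sig`.
#' @param k a single probe id in the signature, or `NULL` (default) for all
#'   signature probes at once.
#' @return Named numeric vector of CF values (length 1 when `k` is given).
#' @export
contribution_fraction <- function(db, members, sig, k = NULL) {
  stopifnot(inherits(db, "ref_db"), inherits(sig, "query_sig"))
  probes <- c(sig$up, sig$down)
  sgn <- c(rep(1, length(sig$up)), rep(-1, length(sig$down)))
  if (!is.null(k)) {
    if (!k %in% probes) stop("probe '", k, "' is not in the signature")
  }
  d <- max_denominator(length(probes), length(db$probe_ids))
  rk <- db$ranks[members, probes, drop = FALSE]           # k_inst x m
  term <- sweep(rk, 2L, sgn, `*`)                          # R(g) s(g) per probe
  c_full <- rowSums(term) / d
  med_c <- stats::median(c_full)
  if (med_c == 0)
    stop("median set score is 0; contribution fraction undefined")
  c_dim <- (rowSums(term) - term) / d                      # diminished per probe
  med_dim <- apply(c_dim, 2L, stats::median)
  cf <- 1 - med_dim / med_c
  names(cf) <- probes
  if (is.null(k)) cf else cf[k]
}

#' Normalize Contribution Fractions within a treatment set
#'
#' `CF*_k = CF_k / max_k(CF_k)`, so the probe contributing most to the
#' connection is exactly 1.0. Negative CF values (probes opposing the
#' connection) are divided by the same positive maximum and so stay negative:
#' the sign information is retained rather than suppressed.
#'
#' @param cf named numeric vector of CF values for one set; at least one must
#'   be positive.
#' @return Named numeric vector of CF* values with `max == 1`.
#' @export
normalize_contributions <- function(cf) {
  if (!length(cf)) stop("no contribution fractions supplied")
  mx <- max(cf)
  if (mx <= 0)
    stop("all contribution fractions are <= 0; normalization undefined")
  cf / mx
}

#' Normalized contribution matrix for the top connections
#'
#' Computes `CF*` for every signature probe against each of the strongest
#' connections (ranked by `|Z|`) among the significant results, giving the
#' probes x treatment-sets matrix behind the contribution heatmap. Rows can
#' be ordered by their median contribution and columns alphabetically.
#'
#' @param db a `ref_db`.
#' @param sig a `query_sig` (reconciled internally).
#' @param results a results data.frame from [run_connectivity()]; only rows
#'   with `significant == TRUE` are used.
#' @param mode grouping mode the results were computed under.
#' @param top_n maximum number of connections (columns), default 100.
#' @param sort_rows order rows by decreasing median CF* (`"median"`,
#'   default) or keep signature order (`"signature"`).
#' @param sort_cols order columns alphabetically (`"alpha"`, default) or by
#'   decreasing `|Z|` (`"z"`).
#' @return Numeric matrix, probes x set keys, of CF* values, with attribute
#'   `"cf"` holding the unnormalized CF matrix.
#' @export
contribution_matrix <- function(db, sig, results,
                                mode = c("by_drug_and_cell_line", "by_drug"),
                                top_n = 100L,
                                sort_rows = c("median", "signature"),
                                sort_cols = c("alpha", "z")) {
  mode <- match.arg(mode)
  sort_rows <- match.arg(sort_rows)
  sort_cols <- match.arg(sort_cols)
  if (!nrow(results)) stop("empty results table")
  sig <- reconcile_signature(sig, db)
  keep <- results[results$significant, , drop = FALSE]
  if (!nrow(keep)) stop("no significant connections to attribute")
  keep <- keep[order(-abs(keep$z), keep$set_key, method = "radix"), , drop = FALSE]
  keep <- utils::head(keep, top_n)

  sets <- group_sets(db, mode)
  probes <- c(sig$up, sig$down)
  cf <- vapply(keep$set_key,
               function(key) contribution_fraction(db, sets[[key]], sig),
               numeric(length(probes)))
  cf <- matrix(cf, nrow = length(probes),
               dimnames = list(probes, keep$set_key))
  cfn <- apply(cf, 2L, normalize_contributions)
  cfn <- matrix(cfn, nrow = length(probes),
                dimnames = dimnames(cf))

  if (sort_rows == "median") {
    med <- apply(cfn, 1L, stats::median)
    ord <- order(-med, rownames(cfn), method = "radix")
    cfn <- cfn[ord, , drop = FALSE]
    cf <- cf[ord, , drop = FALSE]
  }
  if (sort_cols == "alpha") {
    ord <- order(colnames(cfn), method = "radix")
    cfn <- cfn[, ord, drop = FALSE]
    cf <- cf[, ord, drop = FALSE]
  }
  attr(cfn, "cf") <- cf
  cfn
}

#' Export a contribution matrix as CSV
#'
#' Spreadsheet-ready layout: first column `probe_id`, one column per
#' treatment set (header = `perturbagen` or `perturbagen|cell_line`), cells
#' CF* to 6 decimal places.
#'
#' @param cfn matrix from [contribution_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contribution_csv <- function(cfn, path) {
  dt <- data.table::data.table(probe_id = rownames(cfn))
  for (cn in colnames(cfn)) dt[[cn]] <- sprintf("%.6f", cfn[, cn])
  data.table::fwrite(dt, path, sep = ",", quote = "auto")
  invisible(path)
}
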