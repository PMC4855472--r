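#' Maximum attainable signed-rank sum for a signature of size m
#'
#' The scoring denominator: the largest value the numerator
#' `sum_i R(g_i) s(g_i)` can take, reached when the signature probes occupy
#' the top m absolute ranks with concordant signs. Equal to
#' `N + (N-1) + ... + (N-m+1)`.
#'
#' @param m signature size (after reconciliation).
#' @param n_probes number of probes N in the reference profiles.
#' @return Integer-valued numeric.
#' @export
#' @examples
#' max_denominator(2, 10)  # 19
max_denominator <- function(m, n_probes) {
  stopifnot(length(m) == 1L, length(n_probes) == 1L)
  if (m < 1L || m > n_probes)
    stop("signature size m = ", m, " must satisfy 1 <= m <= N = ", n_probes)
  m * n_probes - m * (m - 1) / 2
}

# +1/-1/0 sign vector of a signature over the database probe order
signature_sign_vector <- function(sig, probe_ids) {
  s <- numeric(length(probe_ids))
  iu <- match(sig$up, probe_ids)
  idn <- match(sig$down, probe_ids)
  if (anyNA(iu) || anyNA(idn))
    stop("signature contains probe(s) absent from the database; ",
         "run reconcile_signature() first")
  s[iu] <- 1
  s[idn] <- -1
  s
}

#' Connection scores of a signature against reference profiles
#'
#' For each profile the score is `sum_i R(g_i) s(g_i) / D(m, N)` where
#' `R(g)` is the profile's signed rank of probe g, `s(g)` is +1 for up and
#' -1 for down signature probes, and `D` is [max_denominator()]. Scores lie
#' in \[-1, 1\]: +1 means the signature probes are exactly the most strongly,
#' concordantly regulated probes of the profile (a perfect mimic), -1 a
#' perfect reversal. The denominator is an exact integer, so every score is a
#' ratio of integers.
#'
#' @param db a `ref_db`.
#' @param sig a reconciled `query_sig`.
#' @param instance_ids optional subset of instances to score (default: all).
#' @return Named numeric vector of per-instance scores.
#' @export
connection_scores <- function(db, sig, instance_ids = NULL) {
  stopifnot(inherits(db, "ref_db"), inherits(sig, "query_sig"))
  s <- signature_sign_vector(sig, db$probe_ids)
  d <- max_denominator(sig_size(sig), length(db$probe_ids))
  rk <- if (is.null(instance_ids)) db$ranks else db$ranks[instance_ids, , drop = FALSE]
  drop(rk %*% s) / d
}

#' Connection score of a signature against a single profile
#'
#' @param profile named numeric vector of signed ranks (names = probe ids),
#'   or a single-row selection of `db$ranks`.
#' @param sig a `query_sig` whose probes all appear in `names(profile)`.
#' @return Score in \[-1, 1\].
#' @export
connection_score <- function(profile, sig) {
  stopifnot(inherits(sig, "query_sig"), !is.null(names(profile)))
  probes <- c(sig$up, sig$down)
  if (!all(probes %in% names(profile)))
    stop("signature probe(s) missing from profile: ",
         paste(setdiff(probes, names(profile)), collapse = ", "))
  s <- c(rep(1, length(sig$up)), rep(-1, length(sig$down)))
  sum(profile[probes] * s) / max_denominator(length(probes), length(profile))
}

#' Diminished connection score (one signature probe withheld)
#'
#' The connection score recomputed with probe `k`'s term removed from the
#' numerator while the denominator stays the full `D(m, N)`. The difference
#' `c - c*_k = R(k) s(k) / D` is exactly probe k's contribution to the score;
#' the Contribution Fraction statistic is built on this.
#'
#' @param profile named numeric vector of signed ranks.
#' @param sig a `query_sig`.
#' @param k a probe id belonging to the signature.
#' @return Diminished score.
#' @export
diminished_score <- function(profile, sig, k) {
  probes <- c(sig$up, sig$down)
  if (!k %in% probes) stop("probe '", k, "' is not in the signature")
  s <- c(rep(1, length(sig$up)), rep(-1, length(sig$down)))
  keep <- probes != k
  sum(profile[probes[keep]] * s[keep]) /
    max_denominator(length(probes), length(profile))
}

#' Aggregate instance scores into a treatment-set score
#'
#' The set score is the median of the member instance scores (for even
#' counts, the mean of the two middle values). The median was chosen over the
#' mean because random-signature score distributions of small treatment sets
#' can be heavily skewed, where the mean is unstable.
#'
#' @param scores numeric vector of instance scores (non-empty).
#' @return The median score.
#' @export
set_score <- function(scores) {
  if (!length(scores)) stop("cannot aggregate an empty treatment set")
  stats::median(scores)
}

#' Score every treatment set
#'
#' Computes all instance scores once, then aggregates per treatment set under
#' the requested grouping. Per-set evaluation is independent (no shared
#' state), so results do not depend on evaluation order; output rows are
#' sorted by set key.
#'
#' @param db a `ref_db`.
#' @param sig a reconciled `query_sig`.
#' @param mode grouping mode, see [group_sets()].
#' @return data.frame with `set_key`, `perturbagen`, `cell_line`,
#'   `set_size`, `set_score`.
#' @export
score_all_sets <- function(db, sig, mode = c("by_drug_and_cell_line", "by_drug")) {
  mode <- match.arg(mode)
  sets <- group_sets(db, mode)
  inst <- connection_scores(db, sig)
  out <- parse_set_keys(names(sets), mode)
  out$set_size <- vapply(sets, length, 0L)
  out$set_score <- vapply(sets, function(ids) set_score(inst[ids]), 0)
  rownames(out) <- NULL
  out
}
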