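# bulk scorer used by the null-estimation and skewness paths: draws n_random
# random signatures (current RNG state) and returns the treatment-set score
# of each draw against the member profiles.
random_set_scores <- function(db, members, m_up, m_down, n_random,
                              chunk = 2000L) {
  n <- length(db$probe_ids)
  m <- m_up + m_down
  d <- max_denominator(m, n)
  rk <- db$ranks[members, , drop = FALSE]
  k <- nrow(rk)
  out <- numeric(n_random)
  done <- 0L
  while (done < n_random) {
    nb <- min(chunk, n_random - done)
    sgn <- matrix(0, n, nb)
    for (j in seq_len(nb)) {
      idx <- sample_signature_idx(n, m_up, m_down)
      sgn[idx[seq_len(m_up)], j] <- 1
      if (m_down > 0L) sgn[idx[m_up + seq_len(m_down)], j] <- -1
    }
    sc <- rk %*% sgn / d                       # k x nb instance scores
    out[done + seq_len(nb)] <- if (k == 1L) sc[1L, ]
      else apply(sc, 2L, stats::median)
    done <- done + nb
  }
  out
}

#' Estimate the null distribution of a treatment set's score
#'
#' Draws `n_random` random signatures matching the query's up/down sizes
#' ([random_signature()]), scores the treatment set for each, and returns the
#' sample mean and (n-1 denominator) standard deviation of those set scores.
#' These are the parameters of the Gaussian null used by [p_value()].
#' 2000 random signatures give results consistent between runs; increase for
#' more resolution. Uses the current RNG state; seed beforehand.
#'
#' @param db a `ref_db`.
#' @param members character vector of the set's instance ids.
#' @param m_up,m_down up/down sizes of the (reconciled) query signature.
#' @param n_random number of random signatures (>= 2; default 2000).
#' @return A `null_stats` list: `mu`, `sigma`, `n_random`.
#' @export
estimate_null <- function(db, members, m_up, m_down, n_random = 2000L) {
  stopifnot(inherits(db, "ref_db"))
  if (!length(members)) stop("treatment set is empty")
  if (!all(members %in% rownames(db$ranks)))
    stop("unknown instance id(s): ",
         paste(setdiff(members, rownames(db$ranks)), collapse = ", "))
  if (n_random < 2L) stop("n_random must be at least 2")
  scores <- random_set_scores(db, members, m_up, m_down, n_random)
  structure(list(mu = mean(scores), sigma = stats::sd(scores),
                 n_random = as.integer(n_random)),
            class = "null_stats")
}

#' Two-sided connection p-value under the Gaussian null
#'
#' Assuming random-signature set scores are normally distributed with the
#' estimated `mu` and `sigma`, the p-value is the probability that a random
#' score has absolute value at least `|observed|` — the tail areas of the
#' Gaussian on both sides, computed via the normal error function:
#' `p = 1 - Phi((|obs| - mu)/sigma) + Phi((-|obs| - mu)/sigma)`.
#' Direction (mimic vs reverse) is carried separately by the score and
#' Z-score signs.
#'
#' If `sigma` is exactly 0 the null is degenerate at `mu` and the limit value
#' is returned (1 if `|observed| <= |mu|`, else 0) with a warning.
#'
#' @param observed observed set score(s); vectorized.
#' @param null a `null_stats`, or a list/data.frame with `mu` and `sigma`.
#' @return p-value(s) in \[0, 1\].
#' @export
#' @examples
#' p_value(0.2, list(mu = 0, sigma = 0.1))  # 2 * (1 - pnorm(2)) ~ 0.0455
p_value <- function(observed, null) {
  mu <- null$mu; sigma <- null$sigma
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma >= 0)
  a <- abs(observed)
  if (sigma == 0) {
    warning("degenerate null (sigma = 0); returning limit p-value")
    return(ifelse(a <= abs(mu), 1, 0))
  }
  p <- stats::pnorm((a - mu) / sigma, lower.tail = FALSE) +
       stats::pnorm((-a - mu) / sigma)
  pmin(pmax(p, 0), 1)
}

#' Z-score of an observed set score against its null
#'
#' `(observed - mu) / sigma`; the sign is preserved, so positive Z means the
#' treatment mimics the query state and negative Z means it reverses it.
#'
#' @inheritParams p_value
#' @return Z-score(s).
#' @export
z_score <- function(observed, null) {
  if (null$sigma <= 0) stop("z-score undefined for sigma = 0")
  (observed - null$mu) / null$sigma
}

#' Mark and filter significant connections
#'
#' A connection is significant when `p <= alpha / n_sets` — a Bonferroni-style
#' control of the expected number of false-positive sets per run. Optionally
#' filters by connection direction.
#'
#' @param results data.frame with at least `p` and `set_score` columns.
#' @param alpha family-wise significance level in (0, 1); default 0.05.
#' @param n_sets number of treatment sets tested (default `nrow(results)`).
#' @param direction keep `"all"` connections (default), only `"positive"`
#'   (mimicking, `set_score > 0`) or only `"negative"` (reversing).
#' @param significant_only drop non-significant rows?
#' @return `results` with a logical `significant` column (and rows filtered
#'   when requested).
#' @export
significance_filter <- function(results, alpha = 0.05, n_sets = nrow(results),
                                direction = c("all", "positive", "negative"),
                                significant_only = FALSE) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha < 1, n_sets >= 1)
  results$significant <- results$p <= alpha / n_sets
  results <- switch(direction,
                    all = results,
                    positive = results[results$set_score > 0, , drop = FALSE],
                    negative = results[results$set_score < 0, , drop = FALSE])
  if (significant_only) results <- results[results$significant, , drop = FALSE]
  rownames(results) <- NULL
  results
}

#' Run a full connectivity-mapping analysis
#'
#' The main entry point: reconciles the signature with the database, scores
#' every treatment set, estimates each set's random-signature null, and
#' returns scores, Z-scores, p-values and significance calls.
#'
#' Each set's null uses an RNG substream derived from `(seed, set index)`
#' ([substream_seed()]), so results are identical regardless of the order in
#' which sets are evaluated.
#'
#' @param db a `ref_db`.
#' @param sig a `query_sig` (reconciled internally).
#' @param mode grouping mode, see [group_sets()].
#' @param n_random random signatures per set null (default 2000).
#' @param alpha family-wise significance level (default 0.05; threshold is
#'   `alpha / n_sets`).
#' @param seed master integer seed (mandatory: runs must be reproducible).
#' @param direction direction filter passed to [significance_filter()].
#' @param order sort rows by `"z_desc"` (default), `"z_asc"` or `"set_key"`.
#' @param progress_every log progress every this many sets (0 = silent).
#' @return data.frame with columns `set_key`, `perturbagen`, `cell_line`,
#'   `set_size`, `set_score`, `z`, `p`, `significant`.
#' @export
run_connectivity <- function(db, sig, mode = c("by_drug_and_cell_line", "by_drug"),
                             n_random = 2000L, alpha = 0.05, seed,
                             direction = c("all", "positive", "negative"),
                             order = c("z_desc", "z_asc", "set_key"),
                             progress_every = 0L) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  direction <- match.arg(direction)
  if (missing(seed)) stop("a master seed is required for reproducible runs")
  sig <- reconcile_signature(sig, db)
  sets <- group_sets(db, mode)
  res <- score_all_sets(db, sig, mode)
  m_up <- length(sig$up); m_down <- length(sig$down)

  n_sets <- length(sets)
  res$z <- NA_real_; res$p <- NA_real_
  for (i in seq_len(n_sets)) {
    null <- with_seed(substream_seed(seed, i),
                      estimate_null(db, sets[[i]], m_up, m_down, n_random))
    res$z[i] <- z_score(res$set_score[i], null)
    res$p[i] <- p_value(res$set_score[i], null)
    if (progress_every > 0L && i %% progress_every == 0L)
      .log("scored ", i, "/", n_sets, " treatment sets")
  }
  res <- significance_filter(res, alpha = alpha, n_sets = n_sets,
                             direction = direction)
  res <- switch(order,
                z_desc = res[order(-res$z, res$set_key, method = "radix"), , drop = FALSE],
                z_asc  = res[order(res$z, res$set_key, method = "radix"), , drop = FALSE],
                set_key = res[order(res$set_key, method = "radix"), , drop = FALSE])
  rownames(res) <- NULL
  attr(res, "run") <- list(signature = sig$name, mode = mode,
                           n_random = as.integer(n_random), alpha = alpha,
                           seed = seed, n_sets = n_sets,
                           threshold = alpha / n_sets,
                           m_up = m_up, m_down = m_down)
  res
}
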