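#' Construct a query signature
#'
#' A query signature is a pair of probe-id lists: probes up-regulated and
#' probes down-regulated in the condition of interest. The two lists must be
#' disjoint and jointly non-empty; duplicates within a list are collapsed with
#' a warning. The signature size is `m = |up| + |down|`.
#'
#' @param up,down character vectors of probe ids.
#' @param name signature label.
#' @return A `query_sig` object (list with `name`, `up`, `down`).
#' @export
query_signature <- function(up, down, name = "query") {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up)) {
    warning("duplicate probe(s) in up list collapsed: ",
            paste(unique(up[duplicated(up)]), collapse = ", "))
    up <- unique(up)
  }
  if (anyDuplicated(down)) {
    warning("duplicate probe(s) in down list collapsed: ",
            paste(unique(down[duplicated(down)]), collapse = ", "))
    down <- unique(down)
  }
  both <- intersect(up, down)
  if (length(both))
    stop("probe(s) in both up and down lists: ", paste(both, collapse = ", "))
  if (!length(up) && !length(down)) stop("signature is empty")
  structure(list(name = name, up = up, down = down), class = "query_sig")
}

#' @export
print.query_sig <- function(x, ...) {
  cat("Query signature '", x$name, "': ", length(x$up), " up + ",
      length(x$down), " down probes (m = ", sig_size(x), ")\n", sep = "")
  invisible(x)
}

#' Signature size m
#' @param sig a `query_sig`.
#' @return Integer, `|up| + |down|`.
#' @export
sig_size <- function(sig) length(sig$up) + length(sig$down)

#' Load a query signature from plain-text probe lists
#'
#' Each file holds one probe id per line; blank lines are ignored.
#'
#' @param path_up,path_down file paths for the up and down lists.
#' @param name signature label (defaults to the up-file basename).
#' @return A validated `query_sig`.
#' @export
load_signature <- function(path_up, path_down,
                           name = sub("\\.[^.]*$", "", basename(path_up))) {
  read_list <- function(p) {
    if (!file.exists(p)) stop("signature file not found: ", p)
    x <- trimws(readLines(p))
    x[nzchar(x)]
  }
  query_signature(read_list(path_up), read_list(path_down), name = name)
}

#' Reconcile a signature with a reference database
#'
#' Probes absent from the database are dropped with a message reporting the
#' count; the signature size after reconciliation is what the scoring
#' denominator uses. Erroring out only when nothing remains keeps queries
#' designed on a richer platform usable.
#'
#' @param sig a `query_sig`.
#' @param db a `ref_db`.
#' @return The reconciled `query_sig`.
#' @export
reconcile_signature <- function(sig, db) {
  stopifnot(inherits(sig, "query_sig"), inherits(db, "ref_db"))
  up <- sig$up[sig$up %in% db$probe_ids]
  down <- sig$down[sig$down %in% db$probe_ids]
  dropped <- sig_size(sig) - length(up) - length(down)
  if (length(up) + length(down) == 0L)
    stop("no signature probe is present in the database")
  if (dropped > 0L)
    .log(dropped, " signature probe(s) absent from the database were dropped",
         level = "WARN")
  query_signature(up, down, name = sig$name)
}

# sample m_up + m_down distinct probe indices; first m_up are "up".
# shared by random_signature() and the bulk null-estimation path so both
# consume the RNG identically.
sample_signature_idx <- function(n_probes, m_up, m_down) {
  m <- m_up + m_down
  if (m > n_probes)
    stop("signature size ", m, " exceeds probe universe of ", n_probes)
  if (m < 1L) stop("signature must contain at least one probe")
  sample.int(n_probes, m)
}

#' Draw a random signature of fixed up/down sizes
#'
#' Samples `m_up + m_down` distinct probes uniformly without replacement from
#' the probe universe; the first `m_up` become the up list and the remainder
#' the down list. Random signatures mirror the query's up/down split because
#' the connection score is sign-sensitive; a null built from size-m draws with
#' a different split would not be exchangeable with the query. Uses the
#' current RNG state: seed beforehand (e.g. via [substream_seed()]) for
#' reproducibility.
#'
#' @param m_up,m_down numbers of up and down probes.
#' @param probe_universe character vector of all candidate probe ids
#'   (normally `db$probe_ids`).
#' @return A `query_sig`.
#' @export
random_signature <- function(m_up, m_down, probe_universe) {
  idx <- sample_signature_idx(length(probe_universe), m_up, m_down)
  up <- probe_universe[idx[seq_len(m_up)]]
  down <- if (m_down > 0L) probe_universe[idx[m_up + seq_len(m_down)]] else character()
  query_signature(up, down, name = "random")
}

#' Swap a signature's up and down lists
#'
#' Connection scores are antisymmetric under this flip: every instance and
#' set score negates exactly.
#'
#' @param sig a `query_sig`.
#' @return The flipped `query_sig`.
#' @export
flip_signature <- function(sig) {
  query_signature(sig$down, sig$up, name = paste0(sig$name, "_flipped"))
}

#' Write a signature to a pair of plain-text probe lists
#'
#' @param sig a `query_sig`.
#' @param path_up,path_down output file paths.
#' @return Invisibly, `c(path_up, path_down)`.
#' @export
write_signature <- function(sig, path_up, path_down) {
  writeLines(sig$up, path_up)
  writeLines(sig$down, path_down)
  invisible(c(path_up, path_down))
}
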