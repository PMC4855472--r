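# fixtures are built in code: no data files

# wrap a signed-rank matrix (instances x probes) into a ref_db object
manual_db <- function(ranks, perturbagen = rep("drugA", nrow(ranks)),
                      cell_line = rep("CL1", nrow(ranks))) {
  n <- ncol(ranks)
  probe_ids <- colnames(ranks)
  if (is.null(probe_ids)) {
    probe_ids <- paste0("p", seq_len(n))
    colnames(ranks) <- probe_ids
  }
  ids <- rownames(ranks)
  if (is.null(ids)) {
    ids <- paste0("inst", seq_len(nrow(ranks)))
    rownames(ranks) <- ids
  }
  storage.mode(ranks) <- "integer"
  structure(list(probe_ids = probe_ids, ranks = ranks,
                 meta = data.frame(instance_id = ids,
                                   perturbagen = perturbagen,
                                   cell_line = cell_line,
                                   dose = "10uM", time = "24h",
                                   plate_id = "plate001",
                                   stringsAsFactors = FALSE)),
            class = "ref_db")
}

# the worked 10-probe profile: R(p1)=+10, R(p2)=-9, R(p3)=+4, remaining
# absolute ranks {1,2,3,5,6,7,8} on p4..p10
example_profile10 <- function() {
  r <- c(p1 = 10, p2 = -9, p3 = 4, p4 = 1, p5 = -2, p6 = 3, p7 = 5,
         p8 = -6, p9 = 7, p10 = 8)
  stopifnot(identical(unname(sort(abs(r))), as.numeric(1:10)))
  r
}

example_db10 <- function() manual_db(rbind(inst1 = example_profile10()))

# a uniformly random signed permutation of 1..n (a pure-noise profile)
random_profile <- function(n) {
  r <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
  names(r) <- paste0("p", seq_len(n))
  r
}

# direct-summation oracle for the connection score: explicit loop over
# signature probes, no matrix algebra shared with the implementation
oracle_score <- function(profile, up, down, n = length(profile)) {
  m <- length(up) + length(down)
  denom <- sum(n - seq_len(m) + 1)
  num <- 0
  for (p in up) num <- num + profile[[p]] * 1
  for (p in down) num <- num + profile[[p]] * (-1)
  num / denom
}

# a small Gaussian-noise simulation built through the public generator
small_null_sim <- function(n_sets = 6, n_probes = 200, sizes = c(2, 6),
                           seed = 5, noise_df = Inf, m_up = 5, m_down = 5) {
  cfg <- simulation_config(n_probes = n_probes, n_mimic = 0, n_reverser = 0,
                           n_null = n_sets, cell_lines = "A375",
                           set_size_range = sizes, m_up = m_up,
                           m_down = m_down, noise_df = noise_df, seed = seed)
  simulate_database(cfg)
}
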