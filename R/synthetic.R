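#' Configure a synthetic LINCS-like reference experiment
#'
#' Describes a plate-structured perturbation experiment at desk scale:
#' `n_probes` landmark-style probes (default 978, the L1000 landmark count),
#' a panel of perturbagens assayed in one or more cell lines with replicate
#' instances, and shared controls on every plate. A companion query signature
#' of `m_up` up and `m_down` down probes is drawn from the probe universe;
#' "mimic" perturbagens shift their instances' expression concordantly with
#' that signature (`+effect_size` on up probes, `-effect_size` on down
#' probes), "reverser" perturbagens shift discordantly, and "null"
#' perturbagens are pure noise.
#'
#' Noise is Gaussian by default, or Student-t with `noise_df` degrees of
#' freedom (rescaled to standard deviation `noise_sd`) to emulate the
#' heavy-tailed landscapes in which small treatment sets develop skewed
#' random-score distributions.
#'
#' @param n_probes probe-universe size N (default 978).
#' @param n_mimic,n_reverser,n_null numbers of perturbagens of each role
#'   (defaults 5 / 5 / 30, i.e. 40 compounds).
#' @param cell_lines character vector of cell-line names (default three
#'   LINCS-core lines).
#' @param set_size_range inclusive range of replicate instances per
#'   perturbagen x cell-line set; sizes are drawn uniformly (default 1..50).
#' @param effect_size additive expression shift for planted probes, in units
#'   of `noise_sd` (default 5: strong, clearly recoverable effects).
#' @param noise_sd noise standard deviation (default 1).
#' @param noise_df Student-t degrees of freedom for the noise, or `Inf`
#'   (default) for Gaussian.
#' @param m_up,m_down companion query-signature sizes (default 15 + 15).
#' @param controls_per_plate control instances per plate (default 5).
#' @param plate_capacity maximum treated instances per plate (default 30).
#' @param module_size number of probes in each treatment set's coherent
#'   response module (default: 15% of `n_probes`; 0 disables modules). Every
#'   perturbagen x cell-line set regulates its own random probe module in a
#'   single direction (induction or repression, drawn per set), with
#'   per-probe amplitudes `module_scale * |noise draw|^3` shared by all of
#'   the set's responding instances. The cubed draw makes regulation
#'   magnitudes far more dispersed than well noise, so most module probes
#'   stay buried while the noise law's tail decides how many are strongly,
#'   coherently regulated. Under heavy-tailed noise some sets acquire enough
#'   consistently signed, rank-dominant probes to skew their random-signature
#'   score distribution — structure that real perturbation data shows and
#'   that iid noise cannot produce, because the rank transform caps any
#'   instance-specific outlier.
#' @param module_scale amplitude scale of module effects, in units of
#'   `noise_sd` per cubed unit draw (default 0.05).
#' @param activity_rate probability that a treated instance responds to its
#'   perturbagen at all (default 1: every instance responds). Values below 1
#'   emulate dose/time heterogeneity within treatment sets: inactive
#'   instances receive neither the planted effect nor the module, like an
#'   ineffective dose.
#' @param seed integer seed; the whole simulation is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_probes = 978L,
                              n_mimic = 5L, n_reverser = 5L, n_null = 30L,
                              cell_lines = c("A375", "MCF7", "PC3"),
                              set_size_range = c(1L, 50L),
                              effect_size = 5, noise_sd = 1, noise_df = Inf,
                              m_up = 15L, m_down = 15L,
                              controls_per_plate = 5L, plate_capacity = 30L,
                              module_size = NULL, module_scale = 0.05,
                              activity_rate = 1,
                              seed = 1L) {
  if (is.null(module_size)) module_size <- round(0.15 * n_probes)
  stopifnot(n_probes >= m_up + m_down, n_mimic >= 0, n_reverser >= 0,
            n_null >= 0, n_mimic + n_reverser + n_null >= 1,
            length(set_size_range) == 2L, set_size_range[1] >= 1,
            set_size_range[1] <= set_size_range[2],
            controls_per_plate >= 1L, plate_capacity >= 1L,
            noise_sd > 0, is.infinite(noise_df) || noise_df > 2,
            module_size >= 0L, module_size <= n_probes, module_scale >= 0,
            activity_rate > 0, activity_rate <= 1)
  structure(list(n_probes = as.integer(n_probes),
                 n_mimic = as.integer(n_mimic),
                 n_reverser = as.integer(n_reverser),
                 n_null = as.integer(n_null),
                 cell_lines = as.character(cell_lines),
                 set_size_range = as.integer(set_size_range),
                 effect_size = effect_size, noise_sd = noise_sd,
                 noise_df = noise_df,
                 m_up = as.integer(m_up), m_down = as.integer(m_down),
                 controls_per_plate = as.integer(controls_per_plate),
                 plate_capacity = as.integer(plate_capacity),
                 module_size = as.integer(module_size),
                 module_scale = module_scale,
                 activity_rate = activity_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# noise draws rescaled so sd(noise) == noise_sd even for Student-t
sim_noise <- function(n, cfg) {
  if (is.infinite(cfg$noise_df)) stats::rnorm(n, sd = cfg$noise_sd)
  else stats::rt(n, df = cfg$noise_df) /
    sqrt(cfg$noise_df / (cfg$noise_df - 2)) * cfg$noise_sd
}

#' Simulate a plate-structured perturbation experiment
#'
#' Generates raw expression values, instance metadata, a companion query
#' signature and a truth table under a [simulation_config()]. Instances are
#' laid out on plates of at most `plate_capacity` treated instances plus
#' `controls_per_plate` controls, so replicates of a set share plates (and
#' hence controls) the way replicates do on real plates. The output plugs
#' directly into [build_database()].
#'
#' @param cfg a `sim_config`.
#' @return A `cmap_simulation` list: `values` (probes x instances matrix),
#'   `meta` (instance metadata incl. `is_control`), `truth` (one row per
#'   perturbagen x cell line with `role` in mimic/reverser/null), `query`
#'   (the companion `query_sig`), `probe_ids`, `config`.
#' @export
simulate_database <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    probe_ids <- sprintf("p%04d", seq_len(cfg$n_probes))
    sig_idx <- sample.int(cfg$n_probes, cfg$m_up + cfg$m_down)
    up <- probe_ids[sig_idx[seq_len(cfg$m_up)]]
    down <- probe_ids[sig_idx[cfg$m_up + seq_len(cfg$m_down)]]
    query <- query_signature(up, down, name = "planted_query")

    roles <- c(rep("mimic", cfg$n_mimic), rep("reverser", cfg$n_reverser),
               rep("null", cfg$n_null))
    perts <- sprintf("cpd%02d_%s", seq_along(roles), roles)
    grid <- expand.grid(perturbagen = perts, cell_line = cfg$cell_lines,
                        stringsAsFactors = FALSE)
    grid$role <- roles[match(grid$perturbagen, perts)]
    grid$n_instances <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                               nrow(grid), replace = TRUE)

    # one row per treated instance, in grid order; plates fill sequentially
    trt <- grid[rep(seq_len(nrow(grid)), grid$n_instances), , drop = FALSE]
    n_trt <- nrow(trt)
    plate_of <- (seq_len(n_trt) - 1L) %/% cfg$plate_capacity + 1L
    n_plates <- max(plate_of)

    trt_meta <- data.frame(
      instance_id = sprintf("inst%05d", seq_len(n_trt)),
      perturbagen = trt$perturbagen, cell_line = trt$cell_line,
      dose = "10uM", time = "24h",
      plate_id = sprintf("plate%03d", plate_of),
      is_control = 0L, stringsAsFactors = FALSE)
    ctl_meta <- data.frame(
      instance_id = sprintf("ctrl%05d", seq_len(n_plates * cfg$controls_per_plate)),
      perturbagen = "DMSO", cell_line = "mixed",
      dose = "0", time = "24h",
      plate_id = sprintf("plate%03d", rep(seq_len(n_plates),
                                          each = cfg$controls_per_plate)),
      is_control = 1L, stringsAsFactors = FALSE)
    meta <- rbind(trt_meta, ctl_meta)

    values <- matrix(sim_noise(cfg$n_probes * nrow(meta), cfg),
                     nrow = cfg$n_probes,
                     dimnames = list(probe_ids, meta$instance_id))
    # dose/time activity: inactive instances respond to nothing
    active <- stats::runif(n_trt) <= cfg$activity_rate

    eff <- numeric(cfg$n_probes)
    eff[match(up, probe_ids)] <- cfg$effect_size * cfg$noise_sd
    eff[match(down, probe_ids)] <- -cfg$effect_size * cfg$noise_sd
    mimic_cols <- which(active & trt$role == "mimic")
    rev_cols <- which(active & trt$role == "reverser")
    if (length(mimic_cols)) values[, mimic_cols] <- values[, mimic_cols] + eff
    if (length(rev_cols)) values[, rev_cols] <- values[, rev_cols] - eff

    # coherent per-set response modules: each set induces (or represses) its
    # own random probe module with heavy-tail-capable amplitudes shared by
    # all responding instances
    if (cfg$module_size > 0L && cfg$module_scale > 0) {
      set_of <- paste(trt$perturbagen, trt$cell_line, sep = "|")
      for (s in unique(set_of)) {
        mod_idx <- sample.int(cfg$n_probes, cfg$module_size)
        direction <- sample(c(-1, 1), 1L)
        # regulation magnitudes are far more dispersed than well noise:
        # tail-amplified (cubed) draws keep most module probes buried in the
        # noise while the law's tail decides how many are strongly regulated
        amp <- direction * cfg$module_scale * cfg$noise_sd *
          (abs(sim_noise(cfg$module_size, cfg)) / cfg$noise_sd)^3
        cols <- which(set_of == s & active)
        if (length(cols))
          values[mod_idx, cols] <- values[mod_idx, cols] + amp
      }
    }

    truth <- grid[, c("perturbagen", "cell_line", "role", "n_instances")]
    truth <- truth[order(truth$perturbagen, truth$cell_line, method = "radix"), ]
    rownames(truth) <- NULL

    structure(list(values = values, meta = meta, truth = truth,
                   query = query, probe_ids = probe_ids, config = cfg),
              class = "cmap_simulation")
  })
}

#' @export
print.cmap_simulation <- function(x, ...) {
  cat("Synthetic perturbation experiment\n")
  cat("  probes:    ", length(x$probe_ids), "\n")
  cat("  instances: ", nrow(x$meta), " (", sum(x$meta$is_control == 0L),
      " treated)\n", sep = "")
  cat("  sets:      ", nrow(x$truth), " (",
      sum(x$truth$role == "mimic"), " mimic, ",
      sum(x$truth$role == "reverser"), " reverser)\n", sep = "")
  invisible(x)
}

#' Write a simulation to reference-database input files
#'
#' Emits `expression.tsv` and `metadata.tsv` in the layout expected by
#' [cmd_build_db()] / [read_expression_tsv()], the companion signature as
#' `signature_up.txt` / `signature_down.txt`, and `truth.tsv` with the
#' planted roles.
#'
#' @param sim a `cmap_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cmap_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.table::as.data.table(sim$values)
  expr <- cbind(data.table::data.table(probe_id = rownames(sim$values)), expr)
  data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  write_signature(sim$query, file.path(dir, "signature_up.txt"),
                  file.path(dir, "signature_down.txt"))
  invisible(dir)
}

#' Pearson's moment coefficient of skewness
#'
#' `gamma = m3 / m2^(3/2)` with population (biased) central moments. The
#' statistic behind the choice of median aggregation: treatment sets whose
#' random-signature score distribution has `gamma > 1` are heavily skewed and
#' their mean score is a poor summary.
#'
#' @param xs numeric vector, length >= 3, with positive variance.
#' @return The skewness coefficient.
#' @export
#' @examples
#' pearson_skewness(c(-1, 0, 1))  # 0
pearson_skewness <- function(xs) {
  if (length(xs) < 3L) stop("need at least 3 observations")
  m <- mean(xs)
  m2 <- mean((xs - m)^2)
  if (m2 == 0) stop("zero variance; skewness undefined")
  mean((xs - m)^3) / m2^1.5
}

#' Skewness landscape of random-signature set scores
#'
#' For every treatment set, draws `n_random` random signatures, computes the
#' set score of each, and records the Pearson moment skewness of that score
#' distribution together with the set size. On heavy-tailed data a
#' substantial fraction of small sets (sizes roughly 3-50) exceeds
#' `gamma > 1`, the regime in which median aggregation is preferred over the
#' mean.
#'
#' @param db a `ref_db`.
#' @param mode grouping mode, see [group_sets()].
#' @param m_up,m_down random-signature sizes.
#' @param n_random draws per set (default 2000).
#' @param seed master seed; per-set substreams as in [run_connectivity()].
#' @return data.frame with `set_key`, `set_size`, `gamma`.
#' @export
skew_landscape <- function(db, mode = c("by_drug_and_cell_line", "by_drug"),
                           m_up, m_down, n_random = 2000L, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a master seed is required")
  sets <- group_sets(db, mode)
  gamma <- vapply(seq_along(sets), function(i) {
    scores <- with_seed(substream_seed(seed, i),
                        random_set_scores(db, sets[[i]], m_up, m_down, n_random))
    pearson_skewness(scores)
  }, 0)
  data.frame(set_key = names(sets),
             set_size = vapply(sets, length, 0L),
             gamma = gamma, row.names = NULL, stringsAsFactors = FALSE)
}
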