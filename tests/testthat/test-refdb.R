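test_that("differential profile is treated minus the control summary", {
  expect_equal(differential_profile(c(2, 0, 1), cbind(c(1, 0, 1), c(1, 0, 3))),
               c(1, 0, -1))
  expect_equal(differential_profile(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(differential_profile(c(4, 4), cbind(c(0, 0), c(0, 100), c(0, 200)),
                                    aggregate = "median"),
               c(4, 4 - 100))
  expect_error(differential_profile(c(1, 2), matrix(numeric(0), nrow = 2),
                                    plate_id = "plateX"),
               "plateX")
  expect_error(differential_profile(c(1, 2, 3), cbind(c(1, 2))), "mismatch")
})

test_that("signed ranks follow |d| order and carry the sign of d", {
  expect_identical(signed_rank(c(0.5, -2, 1)), c(1L, -3L, 2L))
  expect_identical(signed_rank(c(-1, -2, -3)), c(-1L, -2L, -3L))
  # idempotence on rank-valued input
  r <- c(2L, -4L, 1L, 3L, -5L)
  expect_identical(signed_rank(r), r)
})

test_that("signed-rank ties break by ascending probe index and zeros rank lowest with + sign", {
  # three exact zeros take ranks 1..3 in index order, all positive
  expect_identical(signed_rank(c(0, 0, 0, -1)), c(1L, 2L, 3L, -4L))
  # tied |d| with opposite signs: earlier index gets the smaller rank
  expect_identical(signed_rank(c(2, -2, 1)), c(2L, -3L, 1L))
})

test_that("signed ranks are invariant under strictly increasing odd transforms", {
  set.seed(42)
  for (i in 1:50) {
    d <- rnorm(sample(3:40, 1))
    expect_identical(signed_rank(d^3), signed_rank(d))
    expect_identical(signed_rank(d * 7.5), signed_rank(d))
  }
})

make_batch <- function() {
  probes <- paste0("p", 1:6)
  meta <- data.frame(
    instance_id = c("t1", "t2", "c1", "c2"),
    perturbagen = c("A", "B", "DMSO", "DMSO"),
    cell_line = c("X", "X", "X", "X"),
    dose = "10uM", time = "24h", plate_id = "pl1",
    is_control = c(0L, 0L, 1L, 1L), stringsAsFactors = FALSE)
  set.seed(1)
  values <- matrix(rnorm(6 * 4), nrow = 6,
                   dimnames = list(probes, meta$instance_id))
  list(values = values, meta = meta)
}

test_that("build_database makes one signed-permutation profile per treated instance", {
  b <- make_batch()
  db <- build_database(b$values, b$meta)
  expect_s3_class(db, "ref_db")
  expect_identical(nrow(db$ranks), 2L)
  expect_setequal(rownames(db$ranks), c("t1", "t2"))
  # controls consumed, not stored
  expect_false(any(c("c1", "c2") %in% db$meta$instance_id))
  # permutation invariant
  for (i in 1:2) expect_identical(unname(sort(abs(db$ranks[i, ]))), 1:6)
  # profiles match the manual pipeline
  d <- differential_profile(b$values[, "t1"], b$values[, c("c1", "c2")])
  expect_identical(unname(db$ranks["t1", ]), signed_rank(d))
})

test_that("build_database rejects degenerate batches", {
  b <- make_batch()
  all_ctrl <- b$meta; all_ctrl$is_control <- 1L
  expect_error(build_database(b$values, all_ctrl), "non-control")
  orphan <- b$meta
  orphan$plate_id[orphan$instance_id == "t2"] <- "pl99"
  expect_error(build_database(b$values, orphan), "t2")
  nav <- b$values; nav[1, 1] <- NA
  expect_error(build_database(nav, b$meta), "missing")
})

test_that("databases round-trip through the directory format unchanged", {
  sim <- small_null_sim(n_sets = 3, n_probes = 40, sizes = c(1, 3))
  db <- build_database(sim$values, sim$meta)
  dir <- withr::local_tempdir()
  save_refdb(db, dir)
  expect_true(all(file.exists(file.path(dir, c("probes.txt", "ranks.tsv.gz",
                                               "instances.tsv")))))
  db2 <- load_refdb(dir)
  expect_identical(db2$probe_ids, db$probe_ids)
  expect_identical(db2$ranks, db$ranks)
  expect_identical(db2$meta$perturbagen, db$meta$perturbagen)
})

test_that("group_sets partitions profiles under both modes", {
  rk <- do.call(rbind, lapply(1:5, function(i) random_profile(8)))
  rownames(rk) <- paste0("i", 1:5)
  db <- manual_db(rk, perturbagen = c("A", "A", "A", "B", "B"),
                  cell_line = c("X", "X", "Y", "X", ""))
  by_dc <- group_sets(db, "by_drug_and_cell_line")
  expect_identical(lengths(by_dc)[["A|X"]], 2L)
  expect_identical(lengths(by_dc)[["A|Y"]], 1L)
  # empty cell line is a distinct category
  expect_true("B|" %in% names(by_dc))
  by_d <- group_sets(db, "by_drug")
  expect_identical(lengths(by_d)[["A"]], 3L)
  # both modes are partitions and drug sets are unions of drug/cell sets
  expect_setequal(unlist(by_dc), db$meta$instance_id)
  expect_setequal(unlist(by_d), db$meta$instance_id)
  expect_identical(anyDuplicated(unlist(by_dc)), 0L)
  for (key in names(by_dc)) {
    drug <- sub("\\|.*$", "", key)
    expect_true(all(by_dc[[key]] %in% by_d[[drug]]))
  }
})

test_that("compound filtering retains exactly the approved perturbagens", {
  rk <- do.call(rbind, lapply(1:5, function(i) random_profile(8)))
  db <- manual_db(rk, perturbagen = c("A", "A", "B", "B", "B"))
  expect_identical(nrow(filter_by_compound_list(db, c("A", "B"))$ranks), 5L)
  fA <- filter_by_compound_list(db, "A")
  expect_identical(nrow(fA$ranks), 2L)
  expect_identical(fA$probe_ids, db$probe_ids)
  expect_error(filter_by_compound_list(db, character(0)), "no profiles")
  expect_error(filter_by_compound_list(db, "a"), "no profiles")
  expect_identical(nrow(filter_by_compound_list(db, "a", case_fold = TRUE)$ranks), 2L)
})
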