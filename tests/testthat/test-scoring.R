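test_that("the scoring denominator is the top-m rank sum", {
  expect_equal(max_denominator(1, 10), 10)
  expect_equal(max_denominator(2, 10), 19)
  expect_equal(max_denominator(10, 10), 55)
  for (n in c(5, 100, 978)) expect_equal(max_denominator(n, n), n * (n + 1) / 2)
  expect_error(max_denominator(11, 10), "1 <= m <= N")
  expect_error(max_denominator(0, 10), "1 <= m <= N")
})

test_that("connection scores reproduce exact hand-computed ratios", {
  prof <- example_profile10()
  expect_equal(connection_score(prof, query_signature("p1", "p2")), 1)
  expect_equal(connection_score(prof, query_signature("p2", "p1")), -1)
  expect_equal(connection_score(prof, query_signature("p3", character(0))), 0.4)
  expect_equal(connection_score(prof, query_signature(c("p1", "p3"), character(0))),
               14 / 19)
  # database path gives the identical value
  db <- example_db10()
  expect_equal(unname(connection_scores(db, query_signature("p3", character(0)))),
               0.4)
  expect_error(connection_score(prof, query_signature("nope", character(0))),
               "nope")
})

test_that("matrix scoring agrees bit-exactly with the direct-summation oracle", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(8:30, 1)
    prof <- random_profile(n)
    m_up <- sample(0:3, 1)
    m_down <- sample(if (m_up == 0) 1:3 else 0:3, 1)
    probes <- sample(names(prof), m_up + m_down)
    sig <- query_signature(head(probes, m_up), tail(probes, m_down))
    db <- manual_db(rbind(i1 = prof))
    expect_identical(unname(connection_scores(db, sig)),
                     unname(oracle_score(prof, sig$up, sig$down)))
    expect_identical(connection_score(prof, sig),
                     unname(oracle_score(prof, sig$up, sig$down)))
  }
})

test_that("diminished scores drop one term and keep the full denominator", {
  prof <- example_profile10()
  sig <- query_signature(c("p1", "p3"), character(0))
  expect_equal(diminished_score(prof, sig, "p1"), 4 / 19)
  expect_equal(diminished_score(prof, sig, "p3"), 10 / 19)
  # m = 1: numerator empties
  expect_equal(diminished_score(prof, query_signature("p7", character(0)), "p7"), 0)
  expect_error(diminished_score(prof, sig, "p9"), "not in the signature")
  # algebraic identity c - c*_k = R(k) s(k) / D
  set.seed(7)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    p <- random_profile(n)
    probes <- sample(names(p), 4)
    sig <- query_signature(probes[1:2], probes[3:4])
    d <- max_denominator(4, n)
    for (k in probes) {
      s_k <- if (k %in% sig$up) 1 else -1
      expect_equal(connection_score(p, sig) - diminished_score(p, sig, k),
                   p[[k]] * s_k / d)
    }
  }
})

test_that("set aggregation is the median with mean-of-middle-two for even sizes", {
  expect_equal(set_score(c(0.1, 0.5, 0.2)), 0.2)
  expect_equal(set_score(c(0.1, 0.3)), 0.2)
  expect_equal(set_score(0.7), 0.7)
  expect_error(set_score(numeric(0)), "empty")
  # sort-based oracle
  oracle_median <- function(x) {
    s <- sort(x); k <- length(x)
    if (k %% 2 == 1) s[(k + 1) / 2] else (s[k / 2] + s[k / 2 + 1]) / 2
  }
  set.seed(31)
  for (i in 1:1000) {
    x <- rnorm(sample(1:50, 1))
    expect_identical(set_score(x), oracle_median(x))
  }
})

test_that("flipping the signature negates every instance and set score exactly", {
  sim <- small_null_sim(n_sets = 4, n_probes = 120, sizes = c(1, 6))
  db <- build_database(sim$values, sim$meta)
  sig <- sim$query
  expect_identical(connection_scores(db, flip_signature(sig)),
                   -connection_scores(db, sig))
  a <- score_all_sets(db, sig)
  b <- score_all_sets(db, flip_signature(sig))
  expect_identical(b$set_score, -a$set_score)
})

test_that("scores are bounded by 1 with equality only for top-m concordance", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    p <- random_profile(n)
    probes <- sample(names(p), sample(1:4, 1))
    half <- sample(0:length(probes), 1)
    sig <- query_signature(head(probes, half), tail(probes, length(probes) - half))
    expect_lte(abs(connection_score(p, sig)), 1)
  }
  # maximal concordant case hits the bound exactly; near-misses stay below
  prof <- example_profile10()
  expect_lt(connection_score(prof, query_signature(c("p1", "p9"), "p2")), 1)
  expect_equal(connection_score(prof, query_signature("p1", "p2")), 1)
})

test_that("cubing differential values end-to-end changes no score", {
  set.seed(55)
  n <- 60
  d_mat <- matrix(rnorm(n * 8), nrow = 8)  # 8 instances x 60 probes of differentials
  rk1 <- t(apply(d_mat, 1L, signed_rank))
  rk2 <- t(apply(d_mat^3, 1L, signed_rank))
  colnames(rk1) <- colnames(rk2) <- paste0("p", 1:n)
  expect_identical(rk1, rk2)
  db1 <- manual_db(rk1, perturbagen = rep(c("A", "B"), each = 4))
  db2 <- manual_db(rk2, perturbagen = rep(c("A", "B"), each = 4))
  sig <- query_signature(paste0("p", 1:5), paste0("p", 6:10))
  expect_identical(score_all_sets(db1, sig), score_all_sets(db2, sig))
})

test_that("set scores are independent of database row order", {
  sim <- small_null_sim(n_sets = 5, n_probes = 100, sizes = c(1, 5))
  db <- build_database(sim$values, sim$meta)
  perm <- sample(nrow(db$ranks))
  db2 <- db
  db2$ranks <- db$ranks[perm, , drop = FALSE]
  db2$meta <- db$meta[perm, , drop = FALSE]
  expect_identical(score_all_sets(db, sim$query), score_all_sets(db2, sim$query))
  # single-instance sets equal the instance score
  res <- score_all_sets(db, sim$query)
  inst <- connection_scores(db, sim$query)
  sets <- group_sets(db)
  for (i in which(res$set_size == 1))
    expect_identical(res$set_score[i], unname(inst[sets[[res$set_key[i]]]]))
})
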