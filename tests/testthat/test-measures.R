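test_that("a split controller has zero integrated information", {
  # each controller node depends only on its own past and the sensor
  set.seed(601)
  sn <- "S1"; an <- "A1"; cn <- c("C1", "C2")
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 4))
  alpha <- lapply(cn, function(nm) random_cond_table(nm, 2L, c(sn, nm), c(2L, 2L)))
  beta <- lapply(an, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 3)))
  gamma <- random_cond_table(sn, 2L, c(sn, an), c(2L, 2L))
  j <- compose_two_step_joint(init, alpha, beta, gamma)
  expect_equal(phi_t(j), 0, tolerance = 1e-12)
})

test_that("a deterministic controller swap integrates one bit per term", {
  # effectively one sensor state, uniform controller, swap dynamics
  sn <- "S1"; an <- "A1"; cn <- c("C1", "C2")
  init_p <- numeric(16)
  # point mass on s = 0, a = 0; uniform over the 4 controller states
  init_p[1 + 0 + 0 + c(0, 4, 8, 12)] <- 0.25
  init <- joint_table(init_p, paste0(c(sn, an, cn), "_t"), rep(2L, 4))
  copy_k <- function(nm, gv, from) {
    ng <- 2^length(gv)
    p <- numeric(2 * ng)
    for (g in seq_len(ng)) {
      own <- bitwAnd((g - 1L) %/% 2^(match(from, gv) - 1L), 1L)
      p[2 * (g - 1L) + own + 1L] <- 1
    }
    cond_table(p, nm, 2L, gv, rep(2L, length(gv)))
  }
  # swap: C1' copies C2, C2' copies C1
  alpha <- list(copy_k("C1", c(sn, cn), "C2"), copy_k("C2", c(sn, cn), "C1"))
  beta <- list(cond_table(rep(0.5, 16), "A1", 2L, c(sn, cn), rep(2L, 3)))
  gamma <- copy_k(sn, c(sn, an), sn)
  j <- compose_two_step_joint(init, alpha, beta, gamma)
  expect_equal(phi_t(j), 4, tolerance = 1e-12)   # 1 bit x 2 nodes x 2 slices
})

test_that("closed forms match term-by-term CMI oracles on random systems", {
  set.seed(602)
  for (r in 1:5) {
    j <- rand_small_system()
    pair_t <- marginalize(j, grep("t\\+2$", j$vars, value = TRUE,
                                  invert = TRUE))
    expect_equal(phi_t(j),
                 brute_cmi(pair_t, "C1_t+1", "C2_t", c("C1_t", "S1_t")) +
                   brute_cmi(pair_t, "C2_t+1", "C1_t", c("C2_t", "S1_t")) +
                   {
                     pair2 <- marginalize(j, grep("_t$", j$vars,
                                                  value = TRUE, invert = TRUE))
                     brute_cmi(pair2, "C1_t+2", "C2_t+1",
                               c("C1_t+1", "S1_t+1")) +
                       brute_cmi(pair2, "C2_t+2", "C1_t+1",
                                 c("C2_t+1", "S1_t+1"))
                   }, tolerance = 1e-10)
    expect_equal(psi_s(j),
                 brute_cmi(j, "S1_t+1", "S1_t", "A1_t") +
                   brute_cmi(j, "S1_t+2", "S1_t+1", "A1_t+1"),
                 tolerance = 1e-10)
    expect_equal(psi_a(j),
                 brute_cmi(j, "S1_t+1", "A1_t", "S1_t") +
                   brute_cmi(j, "S1_t+2", "A1_t+1", "S1_t+1"),
                 tolerance = 1e-10)
    expect_equal(psi_r(j),
                 brute_cmi(j, "A1_t+1", "S1_t", c("C1_t", "C2_t")) +
                   brute_cmi(j, "A1_t+2", "S1_t+1", c("C1_t+1", "C2_t+1")),
                 tolerance = 1e-10)
    expect_equal(psi_tif(j),
                 brute_cmi(j, "S1_t+1", c("S1_t", "A1_t")) +
                   brute_cmi(j, "A1_t+1", c("S1_t", "C1_t", "C2_t")) +
                   brute_cmi(j, "C1_t+1", c("C1_t", "C2_t", "S1_t")) +
                   brute_cmi(j, "C2_t+1", c("C1_t", "C2_t", "S1_t")) +
                   brute_cmi(j, "S1_t+2", c("S1_t+1", "A1_t+1")) +
                   brute_cmi(j, "A1_t+2", c("S1_t+1", "C1_t+1", "C2_t+1")) +
                   brute_cmi(j, "C1_t+2", c("C1_t+1", "C2_t+1", "S1_t+1")) +
                   brute_cmi(j, "C2_t+2", c("C1_t+1", "C2_t+1", "S1_t+1")),
                 tolerance = 1e-10)
  }
})

test_that("structural independencies force the corresponding measures to zero", {
  set.seed(603)
  sn <- c("S1", "S2"); an <- c("A1", "A2"); cn <- c("C1", "C2")
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 6))
  # gamma independent of S given A -> psi_S = 0; of A given S -> psi_A = 0
  g_a <- random_cond_table(sn, c(2L, 2L), an, c(2L, 2L))
  g_a_full <- cond_table(loopflow:::.lf_expand(g_a$p,
                                               c(".t1", ".t2", an),
                                               c(".t1", ".t2", sn, an),
                                               rep(2L, 6)),
                         sn, c(2L, 2L), c(sn, an), rep(2L, 4))
  alpha <- lapply(cn, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 4)))
  beta <- lapply(an, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 4)))
  j <- compose_two_step_joint(init, alpha, beta, g_a_full)
  expect_equal(psi_s(j), 0, tolerance = 1e-12)
  expect_gt(psi_a(j), 0)

  g_s <- random_cond_table(sn, c(2L, 2L), sn, c(2L, 2L))
  g_s_full <- cond_table(loopflow:::.lf_expand(g_s$p,
                                               c(".t1", ".t2", sn),
                                               c(".t1", ".t2", sn, an),
                                               rep(2L, 6)),
                         sn, c(2L, 2L), c(sn, an), rep(2L, 4))
  j2 <- compose_two_step_joint(init, alpha, beta, g_s_full)
  expect_equal(psi_a(j2), 0, tolerance = 1e-12)

  # reactive beta (constant in C) -> psi_C = 0; controller-driven -> psi_R = 0
  gamma <- random_cond_table(sn, c(2L, 2L), c(sn, an), rep(2L, 4))
  beta_r <- lapply(an, function(nm) {
    k <- random_cond_table(nm, 2L, sn, c(2L, 2L))
    cond_table(loopflow:::.lf_expand(k$p, c(".tgt", sn), c(".tgt", sn, cn),
                                     rep(2L, 5)),
               nm, 2L, c(sn, cn), rep(2L, 4))
  })
  jr <- compose_two_step_joint(init, alpha, beta_r, gamma)
  expect_equal(psi_c(jr), 0, tolerance = 1e-12)
  expect_gt(psi_r(jr), 0)

  beta_c <- lapply(an, function(nm) {
    k <- random_cond_table(nm, 2L, cn, c(2L, 2L))
    cond_table(loopflow:::.lf_expand(k$p, c(".tgt", cn), c(".tgt", sn, cn),
                                     rep(2L, 5)),
               nm, 2L, c(sn, cn), rep(2L, 4))
  })
  jc <- compose_two_step_joint(init, alpha, beta_c, gamma)
  expect_equal(psi_r(jc), 0, tolerance = 1e-12)
  expect_gt(psi_c(jc), 0)
})

test_that("measures are non-negative and bounded by the total information flow", {
  set.seed(604)
  for (r in 1:60) {
    j <- rand_small_system()
    panel <- measure_panel(j)
    vals <- unlist(panel[1, c("phi_T", "psi_S", "psi_R", "psi_A", "psi_SI",
                              "psi_C", "psi_TIF")])
    expect_true(all(vals >= 0))
    expect_gte(panel$psi_TIF + 1e-10, max(vals))
  }
})

test_that("a fully time-split system has zero total information flow", {
  set.seed(605)
  sn <- "S1"; an <- "A1"; cn <- c("C1", "C2")
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 4))
  # every next-slice node ignores the past entirely
  const_k <- function(nm, gv) {
    q <- stats::runif(1, 0.2, 0.8)
    cond_table(rep(c(q, 1 - q), 2^length(gv)), nm, 2L, gv,
               rep(2L, length(gv)))
  }
  alpha <- lapply(cn, const_k, gv = c(sn, cn))
  beta <- lapply(an, const_k, gv = c(sn, cn))
  gamma <- const_k(sn, c(sn, an))
  j <- compose_two_step_joint(init, alpha, beta, gamma)
  expect_equal(psi_tif(j), 0, tolerance = 1e-12)
  expect_equal(phi_t(j), 0, tolerance = 1e-12)
})

test_that("each closed form equals its KL projection", {
  set.seed(606)
  measures <- c(phi_T = phi_t, psi_S = psi_s, psi_R = psi_r, psi_A = psi_a,
                psi_SI = psi_si, psi_C = psi_c, psi_TIF = psi_tif)
  for (r in 1:5) {
    j <- rand_small_system()
    for (m in names(measures)) {
      pr <- split_projection(j, split_family(j, m))
      expect_true(pr$converged)
      expect_equal(pr$bits, measures[[m]](j), tolerance = 1e-6,
                   info = paste("measure", m, "rep", r))
      expect_equal(sum(pr$projection$p), 1, tolerance = 1e-10)
    }
    # the full (unsplit) family reproduces the joint at zero distance
    pr <- split_projection(j, split_family(j, "full"))
    expect_equal(pr$bits, 0, tolerance = 1e-10)
    expect_equal(pr$projection$p, j$p, tolerance = 1e-8)
  }
})

test_that("a single controller node warns and returns zero integration", {
  set.seed(607)
  sn <- "S1"; an <- "A1"; cn <- "C1"
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 3))
  alpha <- list(random_cond_table("C1", 2L, c(sn, cn), c(2L, 2L)))
  beta <- list(random_cond_table("A1", 2L, c(sn, cn), c(2L, 2L)))
  gamma <- random_cond_table(sn, 2L, c(sn, an), c(2L, 2L))
  j <- compose_two_step_joint(init, alpha, beta, gamma)
  expect_warning(v <- phi_t(j), "single controller")
  expect_identical(v, 0)
})
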