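test_that("random initial policies are valid and respect the masks", {
  set.seed(501)
  for (aname in c("fully_coupled", "controller_driven", "reactive")) {
    arch <- architecture(aname)
    pol <- init_policy(arch)
    for (k in c(pol$alpha, pol$beta, list(pol$init_c))) {
      rows <- matrix(k$p, nrow = prod(k$target_card))
      expect_equal(colSums(rows), rep(1, ncol(rows)), tolerance = 1e-12)
    }
    expect_equal(sum(pol$init_a), 1, tolerance = 1e-12)
    # masked parents are structurally absent from the kernels
    if (aname == "controller_driven") {
      expect_false(any(c("S1", "S2") %in% pol$beta[[1]]$givens))
    }
    if (aname == "reactive") {
      expect_false(any(c("C1", "C2") %in% pol$beta[[1]]$givens))
    }
  }

  set.seed(7); a <- init_policy(architecture("fully_coupled"))
  set.seed(7); b <- init_policy(architecture("fully_coupled"))
  set.seed(8); c <- init_policy(architecture("fully_coupled"))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("the full joint reduces to the loop joint and prices the goal correctly", {
  ch <- cached_channels()
  set.seed(502)
  pol <- init_policy(architecture("fully_coupled"))
  fj <- build_full_joint(pol, ch$sensor, ch$goal)
  lj <- build_loop_joint(pol, ch$sensor)
  # marginalizing G out of the full joint recovers the loop joint
  expect_equal(marginalize(fj, lj$vars)$p, lj$p, tolerance = 1e-12)

  # P(g1) equals the mean of the goal channel under the induced window law
  pg1 <- marginalize(fj, "G")$p[2]
  gt <- ch$goal$table
  win <- marginalize(lj, gt$givens)
  gmat <- matrix(gt$p, nrow = 2)
  expect_equal(pg1, sum(win$p * gmat[2, ]), tolerance = 1e-12)
  expect_equal(pg1, policy_likelihood(pol, ch), tolerance = 1e-12)

  # a point-mass policy prices P(g1) at the forced window
  det <- pol
  det$init_a <- c(1, 0, 0, 0)
  one_hot <- function(k, which_row) {
    rows <- matrix(0, nrow = prod(k$target_card),
                   ncol = prod(c(k$given_card, 1)))
    rows[which_row, ] <- 1
    cond_table(as.vector(rows), k$targets, k$target_card, k$givens,
               k$given_card)
  }
  det$init_c <- one_hot(det$init_c, 1)
  det$alpha <- lapply(det$alpha, one_hot, which_row = 1)
  det$beta <- lapply(det$beta, one_hot, which_row = 1)
  pg1_det <- policy_likelihood(det, ch)
  # forced actions: a = (0,0) at every slice; sensors still follow gamma,
  # so compare against the explicit sum over sensor paths
  sga <- array(ch$sensor$s_given_a$p, c(4, 4))
  gam <- array(ch$sensor$gamma$p, c(4, 4, 4))
  goal_arr <- array(ch$goal$table$p, c(2, rep(4, 6)))
  acc <- 0
  for (s0 in 1:4) for (s1 in 1:4) for (s2 in 1:4) {
    acc <- acc + sga[s0, 1] * gam[s1, s0, 1] * gam[s2, s1, 1] *
      goal_arr[2, s0, 1, s1, 1, s2, 1]
  }
  expect_equal(pg1_det, acc, tolerance = 1e-12)
})

test_that("one EM iteration equals the brute-force full-joint update", {
  ch <- cached_channels()
  for (aname in c("fully_coupled", "controller_driven", "reactive")) {
    set.seed(503)
    pol <- init_policy(architecture(aname))
    upd <- em_iteration(pol, ch)
    bf <- brute_em_iteration(pol, ch)
    expect_equal(attr(upd, "p_g1"), bf$p_g1, tolerance = 1e-12)
    expect_equal(upd$init_a, bf$init_a, tolerance = 1e-12)
    expect_equal(upd$init_c$p, bf$init_c, tolerance = 1e-12)
    for (i in 1:2) {
      expect_equal(upd$beta[[i]]$p, bf$beta[[i]], tolerance = 1e-12,
                   info = paste(aname, "beta", i))
      expect_equal(upd$alpha[[i]]$p, bf$alpha[[i]], tolerance = 1e-12,
                   info = paste(aname, "alpha", i))
    }
  }
})

test_that("a goal channel that is flat in its arguments leaves the policy fixed", {
  ch <- cached_channels()
  flat <- ch
  gt <- ch$goal$table
  # constant survival probability 0.7 in every context
  flat$goal$table <- cond_table(rep(c(0.3, 0.7), prod(gt$given_card)),
                                gt$targets, gt$target_card, gt$givens,
                                gt$given_card)
  set.seed(504)
  pol <- init_policy(architecture("fully_coupled"))
  upd <- em_iteration(pol, flat)
  expect_equal(attr(upd, "p_g1"), 0.7, tolerance = 1e-12)
  expect_equal(upd$init_a, pol$init_a, tolerance = 1e-12)
  expect_equal(upd$init_c$p, pol$init_c$p, tolerance = 1e-12)
  for (i in 1:2) {
    expect_equal(upd$alpha[[i]]$p, pol$alpha[[i]]$p, tolerance = 1e-12)
    expect_equal(upd$beta[[i]]$p, pol$beta[[i]]$p, tolerance = 1e-12)
  }
  # and the likelihood is unchanged by further iterations
  expect_equal(attr(em_iteration(upd, flat), "p_g1"), 0.7, tolerance = 1e-12)
})

test_that("EM likelihood traces are monotone and reproducible", {
  ch <- cached_channels()
  fits <- optimize_policy(ch, architecture("fully_coupled"), n_restarts = 3,
                          min_iters = 30, tol = 1e-7, seed = 11,
                          max_iters = 300)
  for (f in fits) {
    expect_gte(min(diff(f$likelihood_trace)), -1e-12)
    expect_true(f$final_p_g1 > 0 && f$final_p_g1 <= 1)
  }
  # sorted best first
  pg <- vapply(fits, function(f) f$final_p_g1, numeric(1))
  expect_identical(pg, sort(pg, decreasing = TRUE))
  # bit-reproducible under the same seed
  again <- optimize_policy(ch, architecture("fully_coupled"), n_restarts = 3,
                           min_iters = 30, tol = 1e-7, seed = 11,
                           max_iters = 300)
  expect_identical(fits[[1]]$likelihood_trace, again[[1]]$likelihood_trace)
  expect_identical(fits[[1]]$policy$alpha[[1]]$p,
                   again[[1]]$policy$alpha[[1]]$p)
})

test_that("optimized policies beat every constant-action open-loop baseline", {
  ch <- cached_channels()
  fits <- optimize_policy(ch, architecture("fully_coupled"), n_restarts = 4,
                          min_iters = 60, tol = 1e-6, seed = 21,
                          max_iters = 400)
  best <- fits[[1]]$final_p_g1
  # baselines: always play action pair a (both steps), initial components
  # from the sampled coupling
  sga <- array(ch$sensor$s_given_a$p, c(4, 4))
  gam <- array(ch$sensor$gamma$p, c(4, 4, 4))
  goal_arr <- array(ch$goal$table$p, c(2, rep(4, 6)))
  base <- numeric(4)
  for (a in 1:4) {
    acc <- 0
    for (s0 in 1:4) for (s1 in 1:4) for (s2 in 1:4) {
      acc <- acc + sga[s0, a] * gam[s1, s0, a] * gam[s2, s1, a] *
        goal_arr[2, s0, a, s1, a, s2, a]
    }
    base[a] <- acc
  }
  expect_gte(best, max(base) - 1e-9)
})

test_that("restricted optima are not lost by the fully coupled family", {
  # warm-starting the fully coupled EM from the restricted optimum must do
  # at least as well (plain random restarts can invert the ordering)
  ch <- cached_channels()
  for (aname in c("controller_driven", "reactive")) {
    fits <- optimize_policy(ch, architecture(aname), n_restarts = 2,
                            min_iters = 50, tol = 1e-6, seed = 31,
                            max_iters = 300)
    restricted <- fits[[1]]
    # embed the restricted policy into the fully coupled family
    full <- architecture("fully_coupled")
    emb <- restricted$policy
    emb$arch <- full
    widen <- function(k) {
      dense <- loopflow:::.lf_dense_node(k)     # [target, s(4), c(4)]
      cond_table(as.vector(dense), k$targets, 2L,
                 c("S1", "S2", "C1", "C2"), rep(2L, 4))
    }
    emb$alpha <- lapply(emb$alpha, widen)
    emb$beta <- lapply(emb$beta, widen)
    st <- emb
    pg <- policy_likelihood(st, ch)
    for (it in 1:50) st <- em_iteration(st, ch)
    pg_refined <- policy_likelihood(st, ch)
    expect_gte(pg_refined, restricted$final_p_g1 - 1e-9)
    expect_gte(pg_refined, pg - 1e-12)
  }
})

test_that("reactive optimization keeps beta exactly constant in the controller", {
  ch <- cached_channels()
  fits <- optimize_policy(ch, architecture("reactive"), n_restarts = 2,
                          min_iters = 40, tol = 1e-6, seed = 41,
                          max_iters = 200)
  for (i in 1:2) {
    k <- fits[[1]]$policy$beta[[i]]
    expect_identical(k$givens, c("S1", "S2"))
    dense <- loopflow:::.lf_dense_node(k)   # [target, s, c]: constant in c
    for (cc in 2:4) expect_identical(dense[, , cc], dense[, , 1])
  }
})

test_that("fits round-trip through JSON", {
  ch <- cached_channels()
  fits <- optimize_policy(ch, architecture("controller_driven"),
                          n_restarts = 1, min_iters = 10, tol = 1e-4,
                          seed = 51, max_iters = 50)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fits[[1]], f)
  f2 <- read_fit_json(f)
  expect_equal(f2$final_p_g1, fits[[1]]$final_p_g1, tolerance = 1e-15)
  expect_identical(f2$likelihood_trace, fits[[1]]$likelihood_trace)
  expect_identical(f2$policy$beta[[1]]$givens, fits[[1]]$policy$beta[[1]]$givens)
  expect_equal(f2$policy$alpha[[2]]$p, fits[[1]]$policy$alpha[[2]]$p,
               tolerance = 1e-15)
  expect_equal(policy_likelihood(f2$policy, ch), f2$final_p_g1,
               tolerance = 1e-12)
  # tidy/glance accessors
  td <- tidy(fits[[1]])
  expect_identical(nrow(td), length(fits[[1]]$likelihood_trace))
  gl <- glance(fits[[1]])
  expect_identical(gl$architecture, "controller_driven")
})
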