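# Independent brute-force oracles and shared fixtures. Oracles are written
# as plain loops over enumerated outcomes, independent of the package's
# tensor algebra.

# Brute-force conditional mutual information by looping over all outcomes.
brute_cmi <- function(joint, x, y, z = character()) {
  df <- as.data.frame(joint)
  key <- function(d, vars) {
    if (length(vars) == 0L) return(rep("", nrow(d)))
    do.call(paste, c(d[vars], sep = "\r"))
  }
  pxyz <- tapply(df$prob, key(df, c(x, y, z)), sum)
  pxz <- tapply(df$prob, key(df, c(x, z)), sum)
  pyz <- tapply(df$prob, key(df, c(y, z)), sum)
  pz <- if (length(z)) tapply(df$prob, key(df, z), sum) else NULL
  total <- 0
  for (k in names(pxyz)) {
    p <- pxyz[[k]]
    if (p <= 0) next
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    kx <- paste(parts[seq_along(x)], collapse = "\r")
    ky <- paste(parts[length(x) + seq_along(y)], collapse = "\r")
    kz <- if (length(z)) {
      paste(parts[length(x) + length(y) + seq_along(z)], collapse = "\r")
    } else ""
    kxz <- if (length(z)) paste(kx, kz, sep = "\r") else kx
    kyz <- if (length(z)) paste(ky, kz, sep = "\r") else ky
    pzv <- if (length(z)) pz[[kz]] else 1
    total <- total + p * log2(p * pzv / (pxz[[kxz]] * pyz[[kyz]]))
  }
  total
}

# A random two-step system composed from random kernels: 1 sensor node,
# 1 actuator node, 2 controller nodes (4096 joint states).
rand_small_system <- function() {
  sn <- "S1"; an <- "A1"; cn <- c("C1", "C2")
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 4))
  alpha <- lapply(cn, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 3)))
  beta <- lapply(an, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 3)))
  gamma <- random_cond_table(sn, 2L, c(sn, an), rep(2L, 2))
  compose_two_step_joint(init, alpha, beta, gamma)
}

# Full-size random composed system (2 nodes per group), for measure tests.
rand_full_system <- function() {
  sn <- c("S1", "S2"); an <- c("A1", "A2"); cn <- c("C1", "C2")
  init <- random_joint_table(paste0(c(sn, an, cn), "_t"), rep(2L, 6))
  alpha <- lapply(cn, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 4)))
  beta <- lapply(an, function(nm) random_cond_table(nm, 2L, c(sn, cn), rep(2L, 4)))
  gamma <- random_cond_table(sn, c(2L, 2L), c(sn, an), rep(2L, 4))
  compose_two_step_joint(init, alpha, beta, gamma)
}

# A compact corridor track for fast sampling in tests.
small_track <- function() default_track(width = 20, height = 14, corridor = 5,
                                        radius = 6)

# Channels on the small track, sampled once per session and cached.
.lf_test_cache <- new.env(parent = emptyenv())
cached_channels <- function(sensor_length = 1, n_samples = 5e4) {
  key <- paste0("ch_", sensor_length, "_", n_samples)
  if (is.null(.lf_test_cache[[key]])) {
    .lf_test_cache[[key]] <- sample_channels(
      small_track(), sensor_config(sensor_length),
      n_samples = n_samples, seed = 99L)
  }
  .lf_test_cache[[key]]
}

# Brute-force one EM iteration on the full joint (independent of the
# package's reduced-posterior implementation). Returns posterior-conditional
# updates with masked parents marginalized out of the pooled counts.
brute_em_iteration <- function(policy, channels) {
  at <- function(n, s) paste0(n, "_", s)
  sn <- c("S1", "S2"); an <- c("A1", "A2"); cn <- c("C1", "C2")
  fj <- build_full_joint(policy, channels$sensor, channels$goal)
  arr <- array(fj$p, fj$card)
  g_idx <- match("G", fj$vars)
  idx <- as.list(rep(TRUE, length(fj$vars)))
  idx[[g_idx]] <- 2L
  ps <- as.vector(do.call(`[`, c(list(arr), idx)))
  pg1 <- sum(ps)
  q <- joint_table(ps / pg1, fj$vars[-g_idx], fj$card[-g_idx])
  pooled <- function(node, parents) {
    n1 <- marginalize(q, c(at(node, "t+1"), at(parents, "t")))$p
    n2 <- marginalize(q, c(at(node, "t+2"), at(parents, "t+1")))$p
    m <- matrix(n1 + n2, nrow = 2)
    as.vector(sweep(m, 2, colSums(m), "/"))
  }
  bp <- c(if (policy$arch$edges["s_to_a"]) sn, if (policy$arch$edges["c_to_a"]) cn)
  ap <- c(if (policy$arch$edges["s_to_c"]) sn, if (policy$arch$edges["c_to_c"]) cn)
  list(
    p_g1 = pg1,
    init_a = marginalize(q, at(an, "t"))$p,
    init_c = condition_table(q, at(cn, "t"), at(c(an, sn), "t"))$p,
    beta = lapply(an, pooled, parents = bp),
    alpha = lapply(cn, pooled, parents = ap)
  )
}
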