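# Planning as inference: the policy kernels alpha = P(C'_j | parents) and
# beta = P(A'_i | parents), together with the free initial components P(A_t)
# and P(C_t | A_t, S_t), are latent conditional distributions optimized to
# maximize the two-step survival likelihood P(g = 1) by exact-posterior EM
# (equivalent to the information-geometric em-algorithm on this model; the
# likelihood is non-decreasing at every iteration).
#
# The E-step posterior is computed on the reduced variable set
# (S,A,C at t; S,A,C at t+1; A at t+2): C_{t+2} is a leaf of the two-step
# graph, so its posterior conditional given (S_{t+1}, C_{t+1}) equals alpha
# exactly and the pooled slice-2 alpha counts are Q(s', c') * alpha. This is
# algebraically identical to EM on the full joint.

.LF_S_NODES <- c("S1", "S2")
.LF_A_NODES <- c("A1", "A2")
.LF_C_NODES <- c("C1", "C2")

#' Controller architectures
#'
#' An architecture is an edge mask over the four policy connections
#' S->A, C->A, S->C and C->C. The three named architectures are:
#' `fully_coupled` (all edges), `controller_driven` (no S->A: every signal
#' must pass through the controller, no reactive control) and `reactive`
#' (no C->A: the controller has no influence on the actuators).
#'
#' @param name One of `"fully_coupled"`, `"controller_driven"`,
#'   `"reactive"`.
#' @return An object of class `architecture` with fields `name` and `edges`
#'   (named logical vector `s_to_a`, `c_to_a`, `s_to_c`, `c_to_c`).
#' @export
architecture <- function(name = c("fully_coupled", "controller_driven",
                                  "reactive")) {
  name <- match.arg(name)
  edges <- c(s_to_a = TRUE, c_to_a = TRUE, s_to_c = TRUE, c_to_c = TRUE)
  if (name == "controller_driven") edges["s_to_a"] <- FALSE
  if (name == "reactive") edges["c_to_a"] <- FALSE
  structure(list(name = name, edges = edges), class = "architecture")
}

.lf_beta_parents <- function(arch) {
  c(if (arch$edges["s_to_a"]) .LF_S_NODES,
    if (arch$edges["c_to_a"]) .LF_C_NODES)
}

.lf_alpha_parents <- function(arch) {
  c(if (arch$edges["s_to_c"]) .LF_S_NODES,
    if (arch$edges["c_to_c"]) .LF_C_NODES)
}

#' Draw a random initial policy
#'
#' Every free conditional row (alpha, beta, the initial action distribution
#' and the initial controller coupling) is drawn independently from a flat
#' Dirichlet over its outcomes; masked parents are structurally absent from
#' the kernels. Uses the current RNG state.
#'
#' @param arch An [architecture()].
#' @return An object of class `loop_policy` with fields `alpha`, `beta`
#'   (lists of per-node [cond_table()] kernels with timeless base names),
#'   `init_a` (length-4 distribution over the action pair), `init_c`
#'   (P(C | A, S) as a `cond_table`) and `arch`.
#' @export
init_policy <- function(arch) {
  stopifnot(inherits(arch, "architecture"))
  bp <- .lf_beta_parents(arch)
  ap <- .lf_alpha_parents(arch)
  beta <- lapply(.LF_A_NODES, function(nm)
    random_cond_table(nm, 2L, bp, rep(2L, length(bp))))
  alpha <- lapply(.LF_C_NODES, function(nm)
    random_cond_table(nm, 2L, ap, rep(2L, length(ap))))
  ia <- stats::rgamma(4, 1); ia <- ia / sum(ia)
  ic <- random_cond_table(.LF_C_NODES, c(2L, 2L),
                          c(.LF_A_NODES, .LF_S_NODES), rep(2L, 4))
  structure(list(alpha = alpha, beta = beta, init_a = ia, init_c = ic,
                 arch = arch), class = "loop_policy")
}

#' @export
print.loop_policy <- function(x, ...) {
  cat("<loop_policy> architecture: ", x$arch$name, "\n", sep = "")
  invisible(x)
}

# ---- full joint --------------------------------------------------------------

#' Build the full two-step joint including the goal variable
#'
#' Multiplies the optimized components (initial action distribution, fixed
#' initial sensor coupling P(S_t | A_t), initial controller coupling, the
#' time-homogeneous alpha/beta kernels at both transitions and the sampled
#' sensor channel gamma at both transitions) with the sampled goal channel,
#' yielding the joint over all loop variables at slices t, t+1, t+2 and G.
#'
#' @param policy A [init_policy()] object.
#' @param sensor A `sensor_channel` from [sample_channels()].
#' @param goal A `goal_channel` from [sample_channels()].
#' @return A [joint_table()] over 18 binary loop variables and `G`.
#' @export
build_full_joint <- function(policy, sensor, goal) {
  j <- build_loop_joint(policy, sensor)
  g <- goal$table
  fac <- .lf_mult(j$p, j$vars, j$card,
                  g$p, c(g$targets, g$givens), c(g$target_card, g$given_card))
  joint_table(fac$p, fac$vars, fac$card)
}

#' Build the loop-variable joint (goal marginalized away)
#'
#' The two-step joint over sensor, actuator and controller nodes at slices
#' t, t+1, t+2 induced by a policy and the sampled sensor channel. This is
#' the distribution on which the information-flow measures are evaluated.
#'
#' @inheritParams build_full_joint
#' @return A [joint_table()] over 18 binary loop variables.
#' @export
build_loop_joint <- function(policy, sensor) {
  stopifnot(inherits(policy, "loop_policy"), inherits(sensor, "sensor_channel"))
  at <- function(nms, s) paste0(nms, "_", s)
  fac <- list(p = policy$init_a, vars = at(.LF_A_NODES, "t"), card = c(2L, 2L))
  sga <- sensor$s_given_a
  fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
    sga, at(sga$targets, "t"), at(sga$givens, "t")))
  ic <- policy$init_c
  fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
    ic, at(ic$targets, "t"), at(ic$givens, "t")))
  slices <- c("t", "t+1", "t+2")
  for (s in 1:2) {
    for (k in c(policy$beta, policy$alpha, list(sensor$gamma))) {
      fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
        k, at(k$targets, slices[s + 1]), at(k$givens, slices[s])))
    }
  }
  joint_table(fac$p, fac$vars, fac$card)
}

# ---- EM context --------------------------------------------------------------

# Canonical posterior variable order (14 binary variables).
.lf_post_vars <- function() {
  c(paste0(c("S1", "S2", "A1", "A2", "C1", "C2"), "_t"),
    paste0(c("S1", "S2", "A1", "A2", "C1", "C2"), "_t+1"),
    paste0(c("A1", "A2"), "_t+2"))
}

# Gather index: position of each posterior cell in a factor over fvars.
.lf_gather_idx <- function(fvars, post_vars, post_card) {
  as.integer(.lf_expand(seq_len(2^length(fvars)), fvars, post_vars, post_card))
}

# Permutation that brings mvars first, for marginalization by rowSums.
.lf_marg_perm <- function(mvars, post_vars, post_card) {
  pos <- match(mvars, post_vars)
  rest <- setdiff(seq_along(post_vars), pos)
  as.vector(aperm(array(seq_len(prod(post_card)), dim = post_card),
                  c(pos, rest)))
}

.lf_em_context <- function(sensor, goal, arch) {
  pv <- .lf_post_vars()
  pc <- rep(2L, length(pv))
  at <- function(nms, s) paste0(nms, "_", s)

  gam <- sensor$gamma
  g1 <- list(p = gam$p, vars = c(at(gam$targets, "t+1"), at(gam$givens, "t")),
             card = rep(2L, 6))
  g2 <- list(p = gam$p, vars = c(at(gam$targets, "t+2"), at(gam$givens, "t+1")),
             card = rep(2L, 6))
  sga <- sensor$s_given_a
  sga_t <- list(p = sga$p, vars = at(c(sga$targets, sga$givens), "t"),
                card = rep(2L, 4))
  gt <- goal$table
  goal_g1 <- list(p = matrix(gt$p, nrow = 2)[2, ], vars = gt$givens,
                  card = gt$given_card)

  fac <- .lf_mult(g2$p, g2$vars, g2$card, goal_g1$p, goal_g1$vars, goal_g1$card)
  keep <- setdiff(fac$vars, at(.LF_S_NODES, "t+2"))
  fac <- list(p = .lf_marg(fac$p, fac$vars, fac$card, keep), vars = keep,
              card = rep(2L, length(keep)))
  fac <- .lf_mult(fac$p, fac$vars, fac$card, g1$p, g1$vars, g1$card)
  fac <- .lf_mult(fac$p, fac$vars, fac$card, sga_t$p, sga_t$vars, sga_t$card)
  static_full <- .lf_expand(fac$p, fac$vars, pv, pc)

  list(
    post_vars = pv, post_card = pc, static_full = static_full, arch = arch,
    idx_a = .lf_gather_idx(at(.LF_A_NODES, "t"), pv, pc),
    idx_ic = .lf_gather_idx(at(c(.LF_C_NODES, .LF_A_NODES, .LF_S_NODES), "t"),
                            pv, pc),
    idx_b1 = .lf_gather_idx(c(at(.LF_A_NODES, "t+1"),
                              at(c(.LF_S_NODES, .LF_C_NODES), "t")), pv, pc),
    idx_al1 = .lf_gather_idx(c(at(.LF_C_NODES, "t+1"),
                               at(c(.LF_S_NODES, .LF_C_NODES), "t")), pv, pc),
    idx_b2 = .lf_gather_idx(c(at(.LF_A_NODES, "t+2"),
                              at(c(.LF_S_NODES, .LF_C_NODES), "t+1")), pv, pc),
    pm_a = .lf_marg_perm(at(.LF_A_NODES, "t"), pv, pc),
    pm_cas = .lf_marg_perm(at(c(.LF_C_NODES, .LF_A_NODES, .LF_S_NODES), "t"),
                           pv, pc),
    pm_b1 = .lf_marg_perm(c(at(.LF_A_NODES, "t+1"),
                            at(c(.LF_S_NODES, .LF_C_NODES), "t")), pv, pc),
    pm_b2 = .lf_marg_perm(c(at(.LF_A_NODES, "t+2"),
                            at(c(.LF_S_NODES, .LF_C_NODES), "t+1")), pv, pc),
    pm_al1 = .lf_marg_perm(c(at(.LF_C_NODES, "t+1"),
                             at(c(.LF_S_NODES, .LF_C_NODES), "t")), pv, pc),
    pm_sc1 = .lf_marg_perm(at(c(.LF_S_NODES, .LF_C_NODES), "t+1"), pv, pc)
  )
}

# Dense per-node kernel over the full parent set (target, S pair, C pair),
# broadcasting over masked parents.
.lf_dense_node <- function(k) {
  # the timeless target may share its base name with a parent (e.g.
  # P(C1 | S, C)); give it a local alias before expanding
  full <- c(".tgt", "S1", "S2", "C1", "C2")
  array(.lf_expand(k$p, c(".tgt", k$givens), full, rep(2L, 5)),
        dim = c(2, 4, 4))
}

# Joint kernel over both nodes: result [n1, n2, s(4), c(4)].
.lf_joint_nodes <- function(d1, d2) {
  out <- array(0, c(2, 2, 4, 4))
  for (v in 1:2) out[, v, , ] <- d1 * rep(d2[v, , ], each = 2)
  out
}

# Normalize pooled counts into a per-node kernel over the reduced parents.
# counts: [target(2), s(4), c(4)]; parents: character subset of S/C nodes.
.lf_counts_to_kernel <- function(counts, target, parents) {
  keep_s <- any(parents %in% .LF_S_NODES)
  keep_c <- any(parents %in% .LF_C_NODES)
  if (!keep_s) counts <- array(colSums(aperm(counts, c(2, 1, 3))), c(2, 1, 4))
  if (!keep_c) {
    d <- dim(counts)
    counts <- array(rowSums(matrix(counts, nrow = d[1] * d[2])), c(d[1], d[2], 1))
  }
  m <- matrix(counts, nrow = 2)
  m <- sweep(m, 2, colSums(m), "/")
  cond_table(as.vector(m), target, 2L, parents, rep(2L, length(parents)))
}

# One EM iteration given a context and dense kernels; returns updated state.
.lf_em_step <- function(ctx, st) {
  post <- ctx$static_full *
    st$init_a[ctx$idx_a] * st$ic_dense[ctx$idx_ic] *
    st$bjoint[ctx$idx_b1] * st$ajoint[ctx$idx_al1] * st$bjoint[ctx$idx_b2]
  pg1 <- sum(post)
  if (!is.finite(pg1) || pg1 <= 0) {
    stop("posterior normalizer is not positive; non-finite likelihood")
  }
  q <- post / pg1
  marg <- function(perm, n) rowSums(matrix(q[perm], nrow = n))

  m_a <- marg(ctx$pm_a, 4L)
  m_cas <- matrix(marg(ctx$pm_cas, 64L), nrow = 4)      # [c, (a,s)]
  m_b1 <- array(marg(ctx$pm_b1, 64L), c(2, 2, 4, 4))    # [a1', a2', s, c]
  m_b2 <- array(marg(ctx$pm_b2, 64L), c(2, 2, 4, 4))
  m_al1 <- array(marg(ctx$pm_al1, 64L), c(2, 2, 4, 4))  # [c1', c2', s, c]
  m_sc1 <- matrix(marg(ctx$pm_sc1, 16L), nrow = 4)      # [s', c']

  st$init_a <- m_a / sum(m_a)
  ic_m <- sweep(m_cas, 2, colSums(m_cas), "/")
  st$init_c <- cond_table(as.vector(ic_m), .LF_C_NODES, c(2L, 2L),
                          c(.LF_A_NODES, .LF_S_NODES), rep(2L, 4))
  st$ic_dense <- as.vector(ic_m)

  bp <- .lf_beta_parents(ctx$arch)
  ap <- .lf_alpha_parents(ctx$arch)
  # beta: pool posterior counts of both slices per actuator node
  pooled_b <- m_b1 + m_b2
  n_b1 <- apply(pooled_b, c(1, 3, 4), sum)   # node 1: sum over a2'
  n_b2 <- apply(pooled_b, c(2, 3, 4), sum)   # node 2: sum over a1'
  st$beta <- list(.lf_counts_to_kernel(n_b1, "A1", bp),
                  .lf_counts_to_kernel(n_b2, "A2", bp))
  # alpha: slice-1 counts from the posterior; slice-2 counts are
  # Q(s', c') * alpha since C_{t+2} is a leaf
  qsc <- m_sc1                                # [s'(4), c'(4)]
  bcast <- array(rep(as.vector(qsc), each = 2), c(2, 4, 4))
  a_dense <- lapply(st$alpha, .lf_dense_node)
  n_a1 <- apply(m_al1, c(1, 3, 4), sum) + a_dense[[1]] * bcast
  n_a2 <- apply(m_al1, c(2, 3, 4), sum) + a_dense[[2]] * bcast
  st$alpha <- list(.lf_counts_to_kernel(n_a1, "C1", ap),
                   .lf_counts_to_kernel(n_a2, "C2", ap))

  b_dense <- lapply(st$beta, .lf_dense_node)
  a_dense <- lapply(st$alpha, .lf_dense_node)
  st$bjoint <- .lf_joint_nodes(b_dense[[1]], b_dense[[2]])
  st$ajoint <- .lf_joint_nodes(a_dense[[1]], a_dense[[2]])
  st$p_g1 <- pg1
  st
}

.lf_policy_state <- function(policy) {
  b_dense <- lapply(policy$beta, .lf_dense_node)
  a_dense <- lapply(policy$alpha, .lf_dense_node)
  list(init_a = policy$init_a, init_c = policy$init_c,
       ic_dense = policy$init_c$p,
       alpha = policy$alpha, beta = policy$beta,
       bjoint = .lf_joint_nodes(b_dense[[1]], b_dense[[2]]),
       ajoint = .lf_joint_nodes(a_dense[[1]], a_dense[[2]]))
}

.lf_state_policy <- function(st, arch) {
  structure(list(alpha = st$alpha, beta = st$beta, init_a = st$init_a,
                 init_c = st$init_c, arch = arch), class = "loop_policy")
}

#' One exact-posterior EM iteration
#'
#' The E-step conditions the full two-step joint on survival (g = 1); the
#' M-step replaces every free conditional by the corresponding posterior
#' conditional, pooling the expected counts of both time slices for alpha
#' and beta (time homogeneity) and marginalizing masked parents out of the
#' pooled posterior. The sampled channels are never updated.
#'
#' @param policy A [init_policy()] object.
#' @param channels A list with `sensor` and `goal` channels, as returned by
#'   [sample_channels()].
#' @return The updated `loop_policy`, with the pre-update survival
#'   likelihood attached as attribute `p_g1`.
#' @export
em_iteration <- function(policy, channels) {
  ctx <- .lf_em_context(channels$sensor, channels$goal, policy$arch)
  st <- .lf_em_step(ctx, .lf_policy_state(policy))
  out <- .lf_state_policy(st, policy$arch)
  attr(out, "p_g1") <- st$p_g1
  out
}

#' Survival likelihood of a policy
#'
#' @inheritParams em_iteration
#' @return P(g = 1) under the two-step joint.
#' @export
policy_likelihood <- function(policy, channels) {
  ctx <- .lf_em_context(channels$sensor, channels$goal, policy$arch)
  st <- .lf_policy_state(policy)
  sum(ctx$static_full *
        st$init_a[ctx$idx_a] * st$ic_dense[ctx$idx_ic] *
        st$bjoint[ctx$idx_b1] * st$ajoint[ctx$idx_al1] * st$bjoint[ctx$idx_b2])
}

#' Optimize policies by EM with random restarts
#'
#' Runs [em_iteration()] from independently drawn random initial policies.
#' Each restart iterates at least `min_iters` times and stops once the
#' likelihood improvement drops below `tol` (the published protocol is at
#' least 1000 iterations at tolerance 1e-5 with 100 restarts; the desk-scale
#' default is 200/1e-5/20).
#'
#' @param channels Channels from [sample_channels()].
#' @param arch An [architecture()] (or its name).
#' @param n_restarts Number of random initial policies.
#' @param min_iters Minimum EM iterations per restart.
#' @param tol Absolute likelihood-change threshold for stopping.
#' @param seed Optional integer; restart r uses seed `seed + r`.
#' @param max_iters Safety cap on iterations per restart.
#' @return A list of `loop_fit` objects (fields `policy`,
#'   `likelihood_trace`, `final_p_g1`, `n_iters`, `seed`, `converged`),
#'   sorted by final likelihood, best first. Class `loop_fit_list`.
#' @export
optimize_policy <- function(channels, arch = architecture("fully_coupled"),
                            n_restarts = 20L, min_iters = 200L, tol = 1e-5,
                            seed = NULL, max_iters = 2000L) {
  if (is.character(arch)) arch <- architecture(arch)
  stopifnot(n_restarts >= 1, tol > 0)
  ctx <- .lf_em_context(channels$sensor, channels$goal, arch)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    rseed <- if (!is.null(seed)) as.integer(seed + r) else NULL
    if (!is.null(rseed)) set.seed(rseed)
    st <- .lf_policy_state(init_policy(arch))
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      st <- .lf_em_step(ctx, st)
      iter <- iter + 1L
      trace[iter] <- st$p_g1
      if (iter >= 2L && iter >= min_iters &&
          abs(trace[iter] - trace[iter - 1L]) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iters) break
    }
    # trace[i] is the likelihood of the policy entering iteration i; append
    # the likelihood of the final policy so the trace ends at the optimum
    final <- sum(ctx$static_full *
                   st$init_a[ctx$idx_a] * st$ic_dense[ctx$idx_ic] *
                   st$bjoint[ctx$idx_b1] * st$ajoint[ctx$idx_al1] *
                   st$bjoint[ctx$idx_b2])
    trace <- c(trace, final)
    fits[[r]] <- structure(list(
      policy = .lf_state_policy(st, arch), likelihood_trace = trace,
      final_p_g1 = final, n_iters = iter, seed = rseed,
      converged = converged, restart = r,
      sensor_length = channels$sensor$sensor_length,
      architecture = arch$name), class = "loop_fit")
  }
  ord <- order(vapply(fits, function(f) f$final_p_g1, numeric(1)),
               decreasing = TRUE)
  structure(fits[ord], class = "loop_fit_list")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat("<loop_fit> ", x$architecture, ", P(g1) = ", signif(x$final_p_g1, 6),
      " after ", x$n_iters, " iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  invisible(x)
}

#' @export
print.loop_fit_list <- function(x, ...) {
  cat("<loop_fit_list> ", length(x), " restarts, best P(g1) = ",
      signif(x[[1]]$final_p_g1, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted policy optimization
#'
#' @param x A `loop_fit`.
#' @param ... Unused.
#' @return A tibble with one row per EM iteration: `iteration`, `p_g1`.
#' @importFrom generics tidy
#' @export
tidy.loop_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$likelihood_trace),
                 p_g1 = x$likelihood_trace)
}

#' One-row summary of a fitted policy optimization
#'
#' @param x A `loop_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `architecture`, `sensor_length`, `restart`,
#'   `p_g1`, `n_iters`, `converged`.
#' @importFrom generics glance
#' @export
glance.loop_fit <- function(x, ...) {
  tibble::tibble(architecture = x$architecture,
                 sensor_length = x$sensor_length %||% NA_real_,
                 restart = x$restart, p_g1 = x$final_p_g1,
                 n_iters = x$n_iters, converged = x$converged)
}

#' Persist a fit as JSON
#'
#' Stores the full policy tables and the likelihood trace at full double
#' precision.
#'
#' @param fit A `loop_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  ser_k <- function(k) list(p = k$p, targets = k$targets,
                            target_card = k$target_card, givens = k$givens,
                            given_card = k$given_card)
  jsonlite::write_json(list(
    architecture = fit$architecture, sensor_length = fit$sensor_length,
    restart = fit$restart, final_p_g1 = fit$final_p_g1,
    n_iters = fit$n_iters, converged = fit$converged,
    seed = if (is.null(fit$seed)) NA else fit$seed,
    likelihood_trace = fit$likelihood_trace,
    alpha = lapply(fit$policy$alpha, ser_k),
    beta = lapply(fit$policy$beta, ser_k),
    init_a = fit$policy$init_a, init_c = ser_k(fit$policy$init_c)
  ), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a fit written by [write_fit_json()]
#' @param path JSON file path.
#' @return A `loop_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_k <- function(k) cond_table(k$p, k$targets, as.integer(k$target_card),
                                 unlist(k$givens) %||% character(),
                                 as.integer(unlist(k$given_card)))
  arch <- architecture(x$architecture)
  pol <- structure(list(
    alpha = lapply(seq_len(nrow_or_len(x$alpha)), function(i) de_k(pick(x$alpha, i))),
    beta = lapply(seq_len(nrow_or_len(x$beta)), function(i) de_k(pick(x$beta, i))),
    init_a = x$init_a, init_c = de_k(x$init_c), arch = arch),
    class = "loop_policy")
  structure(list(policy = pol, likelihood_trace = x$likelihood_trace,
                 final_p_g1 = x$final_p_g1, n_iters = x$n_iters,
                 seed = if (is.na(x$seed)) NULL else x$seed,
                 converged = x$converged, restart = x$restart,
                 sensor_length = x$sensor_length,
                 architecture = x$architecture), class = "loop_fit")
}

# jsonlite may simplify a list of kernel records into a data frame; these
# helpers index either representation uniformly.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick <- function(x, i) if (is.data.frame(x)) lapply(x, `[[`, i) else x[[i]]

`%||%` <- function(a, b) if (is.null(a)) b else a
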