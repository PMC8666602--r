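# Full-loop world model and its exact marginalization over the world state.
# The marginalized process over (S, A, C) factorizes as
#   P(s,a,c) * prod_i P(a'_i|s,c) * prod_j P(c'_j|s,c) * P(s'|s,a)
# provided the world influences the loop only through the sensors, which is
# the modelling assumption used throughout: the initial coupling is
# P(s,a,c|w) = prod_k P(s_k|w) * P(a,c|s).

#' Draw a random conditional kernel
#'
#' Each row (fixed given-context) is drawn independently from a flat
#' Dirichlet over the target outcomes. Uses the current RNG state.
#'
#' @param targets,givens Variable names.
#' @param target_card,given_card Cardinalities.
#' @return A [cond_table()].
#' @export
random_cond_table <- function(targets, target_card, givens = character(),
                              given_card = integer()) {
  nt <- prod(target_card)
  ng <- prod(c(given_card, 1))
  m <- matrix(stats::rgamma(nt * ng, shape = 1), nrow = nt)
  m <- sweep(m, 2, colSums(m), "/")
  cond_table(as.vector(m), targets, target_card, givens, given_card)
}

#' Draw a random strictly positive joint table
#' @param vars Variable names.
#' @param card Cardinalities.
#' @return A [joint_table()] with all entries positive.
#' @export
random_joint_table <- function(vars, card) {
  p <- stats::rgamma(prod(card), shape = 1)
  joint_table(p, vars, card, normalize = TRUE)
}

#' Construct a random world model
#'
#' Builds the full sensorimotor-loop model including an explicit world state
#' W: the world prior P(w), per-sensor-node emissions P(s_k | w), the
#' loop coupling P(a, c | s) (the world reaches actuators and controller
#' only through the sensors), the world transition P(w' | w, a) and per-node
#' policy kernels alpha and beta. Used as the test oracle for the intrinsic
#' marginalization.
#'
#' @param n_w World-state cardinality.
#' @param n_s,n_a,n_c Numbers of binary sensor, actuator and controller
#'   nodes.
#' @return An object of class `world_model`.
#' @export
random_world_model <- function(n_w = 3L, n_s = 2L, n_a = 2L, n_c = 2L) {
  s_names <- paste0("S", seq_len(n_s))
  a_names <- paste0("A", seq_len(n_a))
  c_names <- paste0("C", seq_len(n_c))
  sac_givens <- c(s_names, c_names)
  structure(list(
    n_w = as.integer(n_w),
    s_names = s_names, a_names = a_names, c_names = c_names,
    p_w = local({ x <- stats::rgamma(n_w, 1); x / sum(x) }),
    s_given_w = lapply(s_names, function(nm)
      random_cond_table(nm, 2L, "W", n_w)),
    ac_given_s = random_cond_table(c(a_names, c_names), rep(2L, n_a + n_c),
                                   s_names, rep(2L, n_s)),
    w_trans = random_cond_table("Wnext", n_w, c("W", a_names),
                                c(n_w, rep(2L, n_a))),
    alpha = lapply(c_names, function(nm)
      random_cond_table(nm, 2L, sac_givens, rep(2L, n_s + n_c))),
    beta = lapply(a_names, function(nm)
      random_cond_table(nm, 2L, sac_givens, rep(2L, n_s + n_c)))
  ), class = "world_model")
}

#' Marginalize the world out of a full loop model
#'
#' Builds the exact one-step joint over (W_t, S_t, A_t, C_t, W_{t+1},
#' S_{t+1}, A_{t+1}, C_{t+1}) implied by a [random_world_model()] and sums
#' over both world states, returning the intrinsic joint over the loop
#' variables at two consecutive slices.
#'
#' @param world A `world_model`.
#' @return A [joint_table()] over the loop variables at slices t and t+1.
#' @export
intrinsic_from_world_model <- function(world) {
  stopifnot(inherits(world, "world_model"))
  at <- function(nms, s) paste0(nms, "_", s)
  # slice t: P(w) * prod_k P(s_k|w) * P(a,c|s)
  fac <- list(p = world$p_w, vars = "W_t", card = world$n_w)
  for (k in world$s_given_w) {
    fac <- .lf_mult_kernel(fac, .lf_rename_kernel(k, at(k$targets, "t"), "W_t"))
  }
  fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
    world$ac_given_s,
    at(world$ac_given_s$targets, "t"), at(world$ac_given_s$givens, "t")))
  # transition: P(w'|w,a) * prod_k P(s'_k|w') * prod_i beta * prod_j alpha
  fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
    world$w_trans, "W_t+1", c("W_t", at(world$a_names, "t"))))
  for (k in world$s_given_w) {
    fac <- .lf_mult_kernel(fac, .lf_rename_kernel(k, at(k$targets, "t+1"), "W_t+1"))
  }
  for (k in c(world$beta, world$alpha)) {
    fac <- .lf_mult_kernel(fac, .lf_rename_kernel(
      k, at(k$targets, "t+1"), at(k$givens, "t")))
  }
  full <- joint_table(fac$p, fac$vars, fac$card)
  keep <- setdiff(full$vars, c("W_t", "W_t+1"))
  marginalize(full, keep)
}
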