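# The seven information-flow measures, each the KL divergence from the
# two-step loop joint to the closest member of a split product family that
# lacks the measured connections. Every measure has a closed form as a sum
# of conditional mutual information terms; split_projection() computes the
# same quantity by explicit minimization over the split family and serves as
# the cross-check.
#
# All measures are evaluated on the loop-variable joint with the goal
# variable marginalized out, in bits.

.lf_measure_nodes <- function(joint, prefix) {
  nm <- grep(paste0("^", prefix, "[0-9]+_t$"), joint$vars, value = TRUE)
  sort(sub("_t$", "", nm))
}

.lf_slice_next <- c("t" = "t+1", "t+1" = "t+2")

# Sum a per-slice CMI over both transitions; f(pair_joint, from, to) -> bits.
.lf_sum_slices <- function(joint, f) {
  total <- 0
  for (from in names(.lf_slice_next)) {
    to <- .lf_slice_next[[from]]
    slice_vars <- joint$vars[endsWith(joint$vars, paste0("_", from)) |
                               endsWith(joint$vars, paste0("_", to))]
    pair <- marginalize(joint, slice_vars)
    total <- total + f(pair, from, to)
  }
  total
}

#' Integrated information of the controller
#'
#' The KL distance from the system to the closest split system in which no
#' controller node receives information from the other controller nodes
#' across time. Closed form: the sum over both transitions and controller
#' nodes j of I(C_j at the next slice; the other controller nodes | C_j,
#' all sensors).
#'
#' @param joint A loop-variable [joint_table()] over slices t, t+1, t+2
#'   (e.g. from [build_loop_joint()] or [compose_two_step_joint()]).
#' @return Integrated information in bits.
#' @export
phi_t <- function(joint) {
  cn <- .lf_measure_nodes(joint, "C")
  sn <- .lf_measure_nodes(joint, "S")
  if (length(cn) < 2L) {
    warning("a single controller node has no cross connections; phi_t is 0")
    return(0)
  }
  .lf_sum_slices(joint, function(pair, from, to) {
    sum(vapply(cn, function(j) {
      cond_mutual_info(pair,
                       x = paste0(j, "_", to),
                       y = paste0(setdiff(cn, j), "_", from),
                       z = c(paste0(j, "_", from), paste0(sn, "_", from)))
    }, numeric(1)))
  })
}

#' Morphological computation
#'
#' Influence of the past sensor state on the next sensor state given the
#' action: sum over both transitions of I(S'; S | A). High values mean the
#' body-environment interaction, not the controller, carries the
#' information.
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_s <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  .lf_sum_slices(joint, function(pair, from, to) {
    cond_mutual_info(pair, paste0(sn, "_", to), paste0(sn, "_", from),
                     paste0(an, "_", from))
  })
}

#' Action effect
#'
#' How strongly the chosen action shapes the next sensor state given the
#' current one: sum over both transitions of I(S'; A | S).
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_a <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  .lf_sum_slices(joint, function(pair, from, to) {
    cond_mutual_info(pair, paste0(sn, "_", to), paste0(an, "_", from),
                     paste0(sn, "_", from))
  })
}

#' Reactive control
#'
#' Direct stimulus-response flow from sensors to actuators bypassing the
#' controller: sum over both transitions and actuator nodes i of
#' I(A_i'; S | C).
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_r <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  cn <- .lf_measure_nodes(joint, "C")
  .lf_sum_slices(joint, function(pair, from, to) {
    sum(vapply(an, function(i) {
      cond_mutual_info(pair, paste0(i, "_", to), paste0(sn, "_", from),
                       paste0(cn, "_", from))
    }, numeric(1)))
  })
}

#' Sensory information
#'
#' Information flow from the sensors into the controller: sum over both
#' transitions and controller nodes j of I(C_j'; S | C).
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_si <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  cn <- .lf_measure_nodes(joint, "C")
  .lf_sum_slices(joint, function(pair, from, to) {
    sum(vapply(cn, function(j) {
      cond_mutual_info(pair, paste0(j, "_", to), paste0(sn, "_", from),
                       paste0(cn, "_", from))
    }, numeric(1)))
  })
}

#' Control
#'
#' Impact of the controller on the actuators: sum over both transitions and
#' actuator nodes i of I(A_i'; C | S). Structurally zero for reactive
#' agents.
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_c <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  cn <- .lf_measure_nodes(joint, "C")
  .lf_sum_slices(joint, function(pair, from, to) {
    sum(vapply(an, function(i) {
      cond_mutual_info(pair, paste0(i, "_", to), paste0(cn, "_", from),
                       paste0(sn, "_", from))
    }, numeric(1)))
  })
}

#' Total information flow
#'
#' KL distance to the fully time-split system: sum over both transitions of
#' I(S'; S, A) plus, per actuator node, I(A_i'; S, C) plus, per controller
#' node, I(C_j'; C, S). Upper-bounds every other measure.
#'
#' @inheritParams phi_t
#' @return Bits.
#' @export
psi_tif <- function(joint) {
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  cn <- .lf_measure_nodes(joint, "C")
  .lf_sum_slices(joint, function(pair, from, to) {
    v <- cond_mutual_info(pair, paste0(sn, "_", to),
                          paste0(c(sn, an), "_", from))
    v <- v + sum(vapply(an, function(i) {
      cond_mutual_info(pair, paste0(i, "_", to), paste0(c(sn, cn), "_", from))
    }, numeric(1)))
    v + sum(vapply(cn, function(j) {
      cond_mutual_info(pair, paste0(j, "_", to), paste0(c(cn, sn), "_", from))
    }, numeric(1)))
  })
}

#' Compute all seven measures
#'
#' @inheritParams phi_t
#' @param ... Metadata columns appended to the result (e.g.
#'   `sensor_length`, `architecture`, `restart`).
#' @return A one-row tibble with columns `phi_T`, `psi_S`, `psi_R`,
#'   `psi_A`, `psi_SI`, `psi_C`, `psi_TIF` (all in bits) plus any metadata.
#' @export
measure_panel <- function(joint, ...) {
  tibble::tibble(
    ...,
    phi_T = phi_t(joint), psi_S = psi_s(joint), psi_R = psi_r(joint),
    psi_A = psi_a(joint), psi_SI = psi_si(joint), psi_C = psi_c(joint),
    psi_TIF = psi_tif(joint)
  )
}

# ---- split families and the projection oracle --------------------------------

#' Split family for a measure
#'
#' Describes the product manifold of split systems for one measure: per
#' next-slice node (group), the reduced parent set at the preceding slice.
#' The slice-t marginal is always a free component.
#'
#' @param joint A loop-variable [joint_table()] (defines the node sets).
#' @param measure One of `"full"`, `"phi_T"`, `"psi_S"`, `"psi_R"`,
#'   `"psi_A"`, `"psi_SI"`, `"psi_C"`, `"psi_TIF"`.
#' @return An object of class `split_family`: a list of components, each
#'   with `node` (target variable names) and `parents`.
#' @export
split_family <- function(joint, measure = "full") {
  measure <- match.arg(measure, c("full", "phi_T", "psi_S", "psi_R",
                                  "psi_A", "psi_SI", "psi_C", "psi_TIF"))
  sn <- .lf_measure_nodes(joint, "S")
  an <- .lf_measure_nodes(joint, "A")
  cn <- .lf_measure_nodes(joint, "C")
  comps <- list()
  for (from in names(.lf_slice_next)) {
    to <- .lf_slice_next[[from]]
    s_par <- paste0(c(sn, an), "_", from)
    ac_par <- paste0(c(sn, cn), "_", from)
    if (measure == "psi_S") s_par <- paste0(an, "_", from)
    if (measure == "psi_A") s_par <- paste0(sn, "_", from)
    if (measure == "psi_TIF") s_par <- character()
    comps[[length(comps) + 1L]] <- list(node = paste0(sn, "_", to),
                                        parents = s_par)
    for (i in an) {
      par <- ac_par
      if (measure == "psi_R") par <- paste0(cn, "_", from)
      if (measure == "psi_C") par <- paste0(sn, "_", from)
      if (measure == "psi_TIF") par <- character()
      comps[[length(comps) + 1L]] <- list(node = paste0(i, "_", to),
                                          parents = par)
    }
    for (j in cn) {
      par <- ac_par
      if (measure == "phi_T") par <- paste0(c(j, sn), "_", from)
      if (measure == "psi_SI") par <- paste0(cn, "_", from)
      if (measure == "psi_TIF") par <- character()
      comps[[length(comps) + 1L]] <- list(node = paste0(j, "_", to),
                                          parents = par)
    }
  }
  structure(list(components = comps,
                 init_vars = joint$vars[endsWith(joint$vars, "_t")],
                 measure = measure), class = "split_family")
}

#' KL projection onto a split family
#'
#' Minimizes D(P || Q) over the split product family by alternating
#' minimization: each component conditional is in turn replaced by the
#' minimizer given the others. Because the objective separates over the
#' components, the sweep converges immediately; the loop iterates until the
#' KL change falls below `tol` to verify.
#'
#' For each measure's family the achieved infimum equals the closed-form
#' conditional-mutual-information sum.
#'
#' @param joint A loop-variable [joint_table()].
#' @param family A [split_family()].
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the KL change.
#' @return A list: `bits` (the infimum), `projection` (the minimizing
#'   [joint_table()]), `n_iter`, `converged`.
#' @export
split_projection <- function(joint, family, max_iter = 5000L, tol = 1e-10) {
  stopifnot(inherits(family, "split_family"))
  build_q <- function(comps, init_p) {
    fac <- list(p = init_p$p, vars = init_p$vars, card = init_p$card)
    for (cm in comps) fac <- .lf_mult_kernel(fac, cm)
    joint_table(.lf_expand(fac$p, fac$vars, joint$vars, joint$card),
                joint$vars, joint$card)
  }
  init_p <- marginalize(joint, family$init_vars)
  # start from the uniform member of the family
  comps <- lapply(family$components, function(cp) {
    nt <- prod(joint$card[match(cp$node, joint$vars)])
    ng <- prod(c(joint$card[match(cp$parents, joint$vars)], 1))
    cond_table(rep(1 / nt, nt * ng), cp$node,
               joint$card[match(cp$node, joint$vars)], cp$parents,
               joint$card[match(cp$parents, joint$vars)])
  })
  kl_prev <- kl_divergence(joint, build_q(comps, init_p))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    comps <- lapply(family$components, function(cp) {
      condition_table(joint, cp$node, cp$parents)
    })
    q <- build_q(comps, init_p)
    kl <- kl_divergence(joint, q)
    if (abs(kl_prev - kl) < tol) {
      converged <- TRUE
      kl_prev <- kl
      break
    }
    kl_prev <- kl
  }
  if (!converged) {
    warning("projection did not converge in ", max_iter,
            " iterations; last KL gap ", format(kl_prev))
  }
  list(bits = kl_prev, projection = q, n_iter = it, converged = converged)
}
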