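# Dense exact algebra of discrete probability tables. Variables are named
# strings following the "X{node}_{slice}" convention (e.g. "S1_t", "C2_t+1");
# probabilities are stored as a numeric vector in column-major order over the
# declared variable order (first variable fastest).

# ---- internal tensor helpers -------------------------------------------------

# Expand `p` (over `vars`) to the larger variable set `to_vars` with
# cardinalities `to_card`, broadcasting over the missing variables.
.lf_expand <- function(p, vars, to_vars, to_card) {
  if (length(vars) == 0L) return(rep(p, prod(to_card)))
  pos <- match(vars, to_vars)
  if (anyNA(pos)) stop("unknown variable(s): ", paste(vars[is.na(pos)], collapse = ", "))
  if (length(vars) == length(to_vars) && all(pos == seq_along(to_vars))) return(p)
  ord <- order(pos)
  arr <- array(p, dim = to_card[pos])
  arr <- aperm(arr, ord)
  sorted_pos <- pos[ord]
  miss <- setdiff(seq_along(to_vars), pos)
  arr <- array(as.vector(arr), dim = c(to_card[sorted_pos], to_card[miss]))
  perm <- match(seq_along(to_vars), c(sorted_pos, miss))
  as.vector(aperm(arr, perm))
}

# Sum `p` (over `vars` with cardinalities `card`) down to `keep`, returned in
# the order of `keep`.
.lf_marg <- function(p, vars, card, keep) {
  if (length(keep) == 0L) return(sum(p))
  pos <- match(keep, vars)
  if (anyNA(pos)) stop("unknown variable(s): ", paste(keep[is.na(pos)], collapse = ", "))
  rest <- setdiff(seq_along(vars), pos)
  arr <- aperm(array(p, dim = card), c(pos, rest))
  if (length(rest) == 0L) return(as.vector(arr))
  rowSums(matrix(as.vector(arr), nrow = prod(card[pos])))
}

# Pointwise product of two factors; result over union(va, vb) with va first.
.lf_mult <- function(pa, va, ca, pb, vb, cb) {
  extra <- setdiff(vb, va)
  vars <- c(va, extra)
  card <- c(ca, cb[match(extra, vb)])
  list(
    p = .lf_expand(pa, va, vars, card) * .lf_expand(pb, vb, vars, card),
    vars = vars, card = card
  )
}

# ---- joint tables ------------------------------------------------------------

#' Create a joint probability table
#'
#' A joint table is a probability distribution over a named, ordered set of
#' discrete variables. Probabilities are stored densely in column-major order
#' over the declared variable order (the first variable varies fastest).
#'
#' @param p Numeric vector of probabilities of length `prod(card)`, or an
#'   array whose dimensions match `card`.
#' @param vars Character vector of unique variable names.
#' @param card Integer vector of cardinalities (one per variable, each >= 2
#'   for loop variables; the goal variable is binary).
#' @param normalize If `TRUE`, rescale `p` to sum to one.
#'
#' @return An object of class `joint_table` with fields `p`, `vars`, `card`.
#' @examples
#' j <- joint_table(rep(1, 8), c("X", "Y", "Z"), c(2L, 2L, 2L), normalize = TRUE)
#' marginalize(j, c("X", "Y"))
#' @export
joint_table <- function(p, vars, card, normalize = FALSE) {
  p <- as.numeric(p)
  card <- as.integer(card)
  if (anyDuplicated(vars)) stop("variable names must be unique")
  if (length(vars) != length(card)) stop("vars and card lengths differ")
  if (length(p) != prod(card)) stop("probability vector has wrong length")
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (normalize) p <- p / sum(p)
  tot <- sum(p)
  if (abs(tot - 1) > 1e-9) stop("probabilities must sum to 1 (got ", format(tot), ")")
  structure(list(p = p, vars = vars, card = card), class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat("<joint_table> ", length(x$vars), " variables, ",
      prod(x$card), " states\n", sep = "")
  cat("  ", paste0(x$vars, "(", x$card, ")", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.joint_table <- function(x, ...) {
  g <- do.call(expand.grid, stats::setNames(lapply(x$card, seq_len), x$vars))
  g$prob <- x$p
  g
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.joint_table <- function(x, ...) tibble::as_tibble(as.data.frame(x))

#' Marginalize a joint table
#'
#' Sums over all variables not listed in `keep`. Normalization is preserved
#' exactly.
#'
#' @param joint A [joint_table()].
#' @param keep Character vector of variable names to retain (order of the
#'   result follows `keep`).
#' @return A `joint_table` over `keep`.
#' @export
marginalize <- function(joint, keep) {
  stopifnot(inherits(joint, "joint_table"))
  pos <- match(keep, joint$vars)
  if (anyNA(pos)) {
    stop("unknown variable(s): ", paste(keep[is.na(pos)], collapse = ", "))
  }
  p <- .lf_marg(joint$p, joint$vars, joint$card, keep)
  structure(list(p = p, vars = keep, card = joint$card[pos]),
            class = "joint_table")
}

#' Condition a joint table
#'
#' Forms the conditional kernel P(targets | givens) from a joint table. All
#' given-contexts must have positive probability; the pipeline guarantees
#' this via add-epsilon smoothing of sampled channels.
#'
#' @param joint A [joint_table()].
#' @param targets,givens Disjoint character vectors of variable names.
#' @return A [cond_table()] whose rows (fixed givens) sum to one.
#' @export
condition_table <- function(joint, targets, givens = character()) {
  stopifnot(inherits(joint, "joint_table"))
  if (length(intersect(targets, givens)) > 0L) {
    stop("targets and givens must be disjoint")
  }
  m <- marginalize(joint, c(targets, givens))
  tcard <- m$card[seq_along(targets)]
  gcard <- m$card[-seq_along(targets)]
  if (length(givens) == 0L) {
    return(cond_table(m$p, targets, tcard, character(), integer()))
  }
  pg <- .lf_marg(m$p, m$vars, m$card, givens)
  if (any(pg <= 0)) {
    stop("zero-probability conditioning context; the strict-positivity ",
         "assumption on loop distributions is violated")
  }
  denom <- .lf_expand(pg, givens, m$vars, m$card)
  cond_table(m$p / denom, targets, tcard, givens, gcard)
}

# ---- conditional tables ------------------------------------------------------

#' Create a conditional probability table
#'
#' Represents a kernel P(targets | givens), stored over `c(targets, givens)`
#' in column-major order. Every given-context (row) must sum to one.
#'
#' @param p Numeric vector over `c(target_card, given_card)` states.
#' @param targets,givens Character vectors of variable names.
#' @param target_card,given_card Integer cardinalities.
#' @return An object of class `cond_table`.
#' @export
cond_table <- function(p, targets, target_card, givens = character(),
                       given_card = integer()) {
  p <- as.numeric(p)
  target_card <- as.integer(target_card)
  given_card <- as.integer(given_card)
  if (length(p) != prod(c(target_card, given_card))) {
    stop("probability vector has wrong length")
  }
  if (any(p < 0)) stop("probabilities must be non-negative")
  rows <- matrix(p, nrow = prod(target_card))
  sums <- colSums(rows)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("conditional rows must each sum to 1")
  }
  structure(list(p = p, targets = targets, target_card = target_card,
                 givens = givens, given_card = given_card),
            class = "cond_table")
}

#' @export
print.cond_table <- function(x, ...) {
  cat("<cond_table> P(", paste(x$targets, collapse = ","), " | ",
      paste(x$givens, collapse = ","), ")\n", sep = "")
  invisible(x)
}

# Rename the variables of a conditional table (used to place timeless kernels
# such as alpha/beta/gamma at concrete time slices).
.lf_rename_kernel <- function(k, target_names, given_names) {
  cond_table(k$p, target_names, k$target_card, given_names, k$given_card)
}

# ---- divergences -------------------------------------------------------------

#' Kullback-Leibler divergence in bits
#'
#' Computes D(p || q) = sum p log2(p / q) over a common variable space.
#' Terms with p = 0 contribute zero; q must be positive wherever p is.
#'
#' @param p,q [joint_table()] objects over the same variables (any order).
#' @return Non-negative divergence in bits; zero iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "joint_table"), inherits(q, "joint_table"))
  if (!setequal(p$vars, q$vars)) stop("mismatched variable spaces")
  qp <- .lf_expand(q$p, q$vars, p$vars, p$card)
  pos <- p$p > 0
  if (any(qp[pos] <= 0)) {
    stop("q assigns zero probability where p is positive; KL undefined")
  }
  sum(p$p[pos] * (log2(p$p[pos]) - log2(qp[pos])))
}

#' Conditional mutual information in bits
#'
#' Computes I(X; Y | Z) from a joint table by the double-sum definition
#' sum P(x,y,z) log2( P(x,y|z) / (P(x|z) P(y|z)) ), with log base 2. An empty
#' `z` yields the plain mutual information I(X; Y).
#'
#' @param joint A [joint_table()].
#' @param x,y,z Disjoint character vectors of variable names (`z` may be
#'   empty).
#' @return Non-negative value in bits; zero iff X and Y are conditionally
#'   independent given Z.
#' @export
cond_mutual_info <- function(joint, x, y, z = character()) {
  if (length(intersect(x, y)) || length(intersect(x, z)) ||
      length(intersect(y, z))) {
    stop("x, y, z must be pairwise disjoint")
  }
  m <- marginalize(joint, c(x, y, z))
  pxyz <- m$p
  pxz <- .lf_marg(m$p, m$vars, m$card, c(x, z))
  pyz <- .lf_marg(m$p, m$vars, m$card, c(y, z))
  exz <- .lf_expand(pxz, c(x, z), m$vars, m$card)
  eyz <- .lf_expand(pyz, c(y, z), m$vars, m$card)
  if (length(z) > 0L) {
    pz <- .lf_marg(m$p, m$vars, m$card, z)
    ez <- .lf_expand(pz, z, m$vars, m$card)
  } else {
    ez <- rep(1, length(pxyz))
  }
  pos <- pxyz > 0
  val <- sum(pxyz[pos] *
               (log2(pxyz[pos]) + log2(ez[pos]) - log2(exz[pos]) - log2(eyz[pos])))
  max(val, 0)
}

#' Entropy of a joint table in bits
#' @param joint A [joint_table()].
#' @return Shannon entropy in bits.
#' @export
table_entropy <- function(joint) {
  pos <- joint$p > 0
  -sum(joint$p[pos] * log2(joint$p[pos]))
}

# ---- sensorimotor-loop composition ------------------------------------------

# Multiply a kernel (cond_table with concrete variable names) into a running
# factor, returning the updated factor.
.lf_mult_kernel <- function(fac, k) {
  .lf_mult(fac$p, fac$vars, fac$card,
           k$p, c(k$targets, k$givens), c(k$target_card, k$given_card))
}

#' Compose the two-step sensorimotor-loop joint
#'
#' Builds the joint distribution over sensor, actuator and controller nodes
#' at three consecutive time slices (t, t+1, t+2) from an initial slice
#' distribution and time-homogeneous kernels: per-controller-node kernels
#' `alpha` P(C_j' | S, C), per-actuator-node kernels `beta` P(A_i' | S, C)
#' and the sensor channel `gamma` P(S' | S, A). The same kernels are used for
#' both transitions (time homogeneity).
#'
#' Kernels carry timeless base names ("S1", "A2", "C1", ...); the composer
#' attaches slice suffixes "_t", "_t+1", "_t+2".
#'
#' @param init A [joint_table()] over the slice-t variables (names suffixed
#'   `_t`).
#' @param alpha List of [cond_table()] kernels, one per controller node.
#' @param beta List of [cond_table()] kernels, one per actuator node.
#' @param gamma A [cond_table()] kernel for the grouped sensor nodes.
#' @param n_steps Number of transitions to unroll (default 2).
#' @return A `joint_table` over `(n_steps + 1)` slices of loop variables.
#' @export
compose_two_step_joint <- function(init, alpha, beta, gamma, n_steps = 2L) {
  stopifnot(inherits(init, "joint_table"))
  slices <- c("t", paste0("t+", seq_len(n_steps)))
  base_t <- sub("_t$", "", init$vars)
  if (any(!grepl("_t$", init$vars))) {
    stop("init variables must carry the slice suffix '_t'")
  }
  fac <- list(p = init$p, vars = init$vars, card = init$card)
  for (s in seq_len(n_steps)) {
    from <- slices[s]
    to <- slices[s + 1L]
    for (k in c(beta, alpha, list(gamma))) {
      kk <- .lf_rename_kernel(k, paste0(k$targets, "_", to),
                              paste0(k$givens, "_", from))
      if (!all(kk$givens %in% fac$vars)) {
        stop("kernel parents ", paste(setdiff(kk$givens, fac$vars), collapse = ", "),
             " not present in the running joint (dimension mismatch)")
      }
      fac <- .lf_mult_kernel(fac, kk)
    }
  }
  joint_table(fac$p, fac$vars, fac$card)
}

# ---- serialization -----------------------------------------------------------

#' Serialize a joint table to JSON
#'
#' Writes the variable space and the flattened probability vector (column
#' major in the declared variable order) at full double precision, so that a
#' read/write round trip is exact.
#'
#' @param joint A [joint_table()].
#' @param path File path for the JSON output.
#' @return `path`, invisibly.
#' @export
write_joint_json <- function(joint, path) {
  jsonlite::write_json(
    list(vars = joint$vars, card = joint$card, p = joint$p),
    path, digits = I(17), auto_unbox = FALSE
  )
  invisible(path)
}

#' Read a joint table from JSON
#' @param path File path written by [write_joint_json()].
#' @return A [joint_table()].
#' @export
read_joint_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  joint_table(x$p, x$vars, as.integer(x$card))
}
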