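#' Correct homodimer co-tracking counts for stochastic double labeling
#'
#' When a homodimerizing receptor is stochastically labeled with two dyes
#' at equal concentrations, only dimers carrying one dye of each color are
#' seen as co-trajectories.  The corrected count divides the observed
#' co-trajectories by the dual-color dimer probability
#' \code{2 * A/(A+B) * B/(A+B)} (with A and B the per-channel trajectory
#' counts); the relative co-locomotion is \code{2 * AB* / (A + B)}.
#'
#' @param A,B Trajectory counts in the two spectral channels (> 0).
#' @param AB Observed co-trajectory count (0 <= AB <= min(A, B)).
#' @return List with \code{AB_star} (corrected co-trajectory count) and
#'   \code{rel_colocomotion}.
#' @examples
#' correct_homodimer_cotracking(100, 100, 10)  # AB* = 20, rel = 0.2
#' @export
correct_homodimer_cotracking <- function(A, B, AB) {
  if (!(A > 0) || !(B > 0)) {
    stop("undefined correction: both channel counts must be > 0",
         call. = FALSE)
  }
  if (AB < 0 || AB > min(A, B)) {
    stop("AB must satisfy 0 <= AB <= min(A, B)", call. = FALSE)
  }
  p_dual <- 2 * (A / (A + B)) * (B / (A + B))
  AB_star <- AB / p_dual
  list(AB_star = AB_star, rel_colocomotion = 2 * AB_star / (A + B))
}

#' Two-dimensional dissociation constant of a heterodimer
#'
#' Mass-action monomer-dimer equilibrium at the membrane for
#' IL-27-induced IL-27Ralpha/GP130 heterodimerization:
#' \deqn{K_D^{2D} = ([GP130] - \alpha [IL27R\alpha]) ([IL27R\alpha] -
#'   \alpha [IL27R\alpha]) / (\alpha [IL27R\alpha])}
#' with \eqn{\alpha} the fraction of (ligand-bound) IL-27Ralpha in complex
#' with GP130.
#'
#' @param gp130,il27ra Surface densities (molecules per um^2).
#' @param alpha Dimerized fraction of IL-27Ralpha, in (0, 1].
#' @return KD2D in um^-2.
#' @examples
#' kd2d_hetero(2, 1, 0.5)  # 1.5
#' @export
kd2d_hetero <- function(gp130, il27ra, alpha) {
  if (!(alpha > 0)) stop("undefined KD2D: alpha must be > 0 (no dimers)",
                         call. = FALSE)
  if (alpha > 1) stop("alpha must be <= 1", call. = FALSE)
  dimer <- alpha * il27ra
  free_gp130 <- gp130 - dimer
  free_il27ra <- il27ra - dimer
  if (free_gp130 < 0 || free_il27ra < 0) {
    stop("invalid input: dimer density exceeds a total receptor density",
         call. = FALSE)
  }
  free_gp130 * free_il27ra / dimer
}

#' Two-dimensional dissociation constant of the GP130 homodimer
#'
#' With \eqn{\alpha} the fraction of GP130 homodimers relative to
#' \eqn{[GP130]/2}, the dimer density is \eqn{D = \alpha [GP130]/2}, the
#' monomer density \eqn{M = [GP130](1 - \alpha)}, and
#' \eqn{K_D^{2D} = M^2 / D = 2 [GP130] (1-\alpha)^2 / \alpha}.
#'
#' @param gp130 Total GP130 surface density (um^-2).
#' @param alpha Homodimerized fraction, in (0, 1].
#' @return KD2D in um^-2.
#' @examples
#' kd2d_homo(2, 0.5)  # 2
#' @export
kd2d_homo <- function(gp130, alpha) {
  if (!(alpha > 0)) stop("undefined KD2D: alpha must be > 0", call. = FALSE)
  if (alpha > 1) stop("alpha must be <= 1", call. = FALSE)
  2 * gp130 * (1 - alpha)^2 / alpha
}

#' Dimerized fractions implied by a KD2D
#'
#' Inverts the monomer-dimer equilibria: given a KD2D and total surface
#' densities, returns the equilibrium dimerized fraction alpha (the root
#' of the mass-action balance in (0, 1]).
#'
#' @param kd2d Dissociation constant (um^-2, >= 0).
#' @param gp130,il27ra Total densities (um^-2).
#' @return Alpha in (0, 1].
#' @export
alpha_hetero <- function(kd2d, gp130, il27ra) {
  ## (G - a R)(R - a R) = kd * a R  =>  R a^2 - (G + R + kd) a + G = 0
  b <- gp130 + il27ra + kd2d
  disc <- b^2 - 4 * il27ra * gp130
  (b - sqrt(disc)) / (2 * il27ra)
}

#' @rdname alpha_hetero
#' @export
alpha_homo <- function(kd2d, gp130) {
  ## G^2 (1-a)^2 = kd * a G / 2  =>  quadratic in a
  if (gp130 <= 0) stop("gp130 must be > 0", call. = FALSE)
  k <- kd2d / (2 * gp130)
  b <- 2 + k
  (b - sqrt(b^2 - 4)) / 2
}

#' KD2D tables from per-cell CSV-style input
#'
#' Vectorized convenience wrappers over the per-cell estimators.  The
#' homodimer table expects columns \code{A}, \code{B}, \code{AB} and
#' \code{gp130_density}; the heterodimer table expects
#' \code{gp130_density}, \code{il27ra_density}, \code{alpha}.
#'
#' @param cells Data frame of per-cell measurements.
#' @return Input with appended estimate columns.
#' @export
kd2d_homo_table <- function(cells) {
  est <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- correct_homodimer_cotracking(cells$A[i], cells$B[i], cells$AB[i])
    ## 2 AB*/(A+B) is the fraction of receptors found in dimers, i.e. the
    ## homodimer fraction alpha relative to [GP130]/2
    data.frame(AB_star = cc$AB_star,
               rel_colocomotion = cc$rel_colocomotion,
               kd2d = kd2d_homo(cells$gp130_density[i],
                                min(cc$rel_colocomotion, 1)))
  })
  cbind(cells, do.call(rbind, est))
}

#' @rdname kd2d_homo_table
#' @export
kd2d_hetero_table <- function(cells) {
  cells$kd2d <- mapply(kd2d_hetero, cells$gp130_density,
                       cells$il27ra_density, cells$alpha)
  cells
}
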