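## Reaction-network construction.
##
## Each model variant expands to a list of elementary mass-action reactions
## with at most two reactants.  A reaction is stored as (i1, i2, rate name,
## statistical factor) plus stoichiometry triplets (species, reaction,
## coefficient).  Statistical factors implement site counting on dimers
## with equivalent GP130-type sites: an empty homodimer binds a STAT at
## 2*k_on, a doubly occupied dimer loses either copy at 2*k_off, and a
## dimer carrying two unphosphorylated STATs phosphorylates one of them at
## 2*q.  The distinct sites of the wild-type IL-27 heterodimer carry no
## such factors.  Internalization is not expanded into reactions: it is a
## uniform removal term over receptor-containing species, first order
## under H1 and proportional to free pSTAT1 + pSTAT3 under H2.

.occ_free_species <- c(S1 = "S1", S3 = "S3", P1 = "pS1", P3 = "pS3")
.occ_on_rate  <- list(a = c(S1 = "k1a_on",  S3 = "k3a_on"),
                      b = c(S1 = "k1b_on",  S3 = "k3b_on"))
.occ_off_rate <- list(a = c(S1 = "k1a_off", S3 = "k3a_off",
                            P1 = "k1a_off", P3 = "k3a_off"),
                      b = c(S1 = "k1b_off", S3 = "k3b_off",
                            P1 = "k1b_off", P3 = "k3b_off"))
.occ_phospho <- c(S1 = "P1", S3 = "P3")

.network_builder <- function() {
  rx <- new.env(parent = emptyenv())
  rx$i1 <- integer(); rx$i2 <- integer()
  rx$rate <- character(); rx$factor <- numeric()
  rx$st_sp <- integer(); rx$st_rx <- integer(); rx$st_co <- numeric()
  rx
}

.add_reaction <- function(rx, i1, i2, rate, factor, stoich) {
  k <- length(rx$i1) + 1L
  rx$i1 <- c(rx$i1, i1)
  rx$i2 <- c(rx$i2, i2)
  rx$rate <- c(rx$rate, rate)
  rx$factor <- c(rx$factor, factor)
  for (s in stoich) {
    rx$st_sp <- c(rx$st_sp, s[["sp"]])
    rx$st_rx <- c(rx$st_rx, k)
    rx$st_co <- c(rx$st_co, s[["co"]])
  }
  invisible(rx)
}

.st <- function(sp, co) list(sp = sp, co = co)

## Reaction template for a (cytokine, variant) topology; rate values are
## referenced by name and bound later.
.build_template <- function(spec) {
  key <- paste("net", spec$cytokine, spec$receptor_variant, sep = "_")
  cached <- .statkin_cache[[key]]
  if (!is.null(cached)) return(cached)

  reg <- build_registry(spec)
  idx <- stats::setNames(seq_len(nrow(reg)), reg$name)
  rx <- .network_builder()
  hypil6 <- spec$cytokine == "HYPIL6"
  chimera <- spec$receptor_variant == "CHIMERA"
  core <- if (hypil6) "D6" else "D27"

  if (hypil6) {
    ## L6 + R1 <-> C1; C1 + C1 <-> D6
    .add_reaction(rx, idx["L6"], idx["R1"], "r1_6_on", 1,
                  list(.st(idx["L6"], -1), .st(idx["R1"], -1), .st(idx["C1"], 1)))
    .add_reaction(rx, idx["C1"], 0L, "r1_6_off", 1,
                  list(.st(idx["C1"], -1), .st(idx["L6"], 1), .st(idx["R1"], 1)))
    .add_reaction(rx, idx["C1"], idx["C1"], "r2_6_on", 1,
                  list(.st(idx["C1"], -2), .st(idx["D6"], 1)))
    .add_reaction(rx, idx["D6"], 0L, "r2_6_off", 1,
                  list(.st(idx["D6"], -1), .st(idx["C1"], 2)))
  } else {
    ## L27 + R2 <-> C2; C2 + R1 <-> D27
    .add_reaction(rx, idx["L27"], idx["R2"], "r1_27_on", 1,
                  list(.st(idx["L27"], -1), .st(idx["R2"], -1), .st(idx["C2"], 1)))
    .add_reaction(rx, idx["C2"], 0L, "r1_27_off", 1,
                  list(.st(idx["C2"], -1), .st(idx["L27"], 1), .st(idx["R2"], 1)))
    .add_reaction(rx, idx["C2"], idx["R1"], "r2_27_on", 1,
                  list(.st(idx["C2"], -1), .st(idx["R1"], -1), .st(idx["D27"], 1)))
    .add_reaction(rx, idx["D27"], 0L, "r2_27_off", 1,
                  list(.st(idx["D27"], -1), .st(idx["C2"], 1), .st(idx["R1"], 1)))
  }

  if (hypil6 || chimera) {
    ## Two equivalent GP130-type sites; dimer occupancy is an unordered
    ## multiset over {E, S1, S3, P1, P3}.
    states <- c(list(c("E", "E")), .homodimer_pairs)
    sname <- function(p) .homodimer_species_name(core, p[1], p[2])
    for (p in states) {
      i_this <- idx[[sname(p)]]
      n_empty <- sum(p == "E")
      ## binding of free unphosphorylated STATs
      if (n_empty > 0) {
        for (s in c("S1", "S3")) {
          pnew <- p
          pnew[match("E", pnew)] <- s
          .add_reaction(rx, i_this, idx[[s]], .occ_on_rate$a[[s]], n_empty,
                        list(.st(i_this, -1), .st(idx[[s]], -1),
                             .st(idx[[sname(pnew)]], 1)))
        }
      }
      ## unbinding and phosphorylation of each occupant type
      for (m in unique(p[p != "E"])) {
        cnt <- sum(p == m)
        pnew <- p
        pnew[match(m, pnew)] <- "E"
        free_sp <- idx[[.occ_free_species[[m]]]]
        .add_reaction(rx, i_this, 0L, .occ_off_rate$a[[m]], cnt,
                      list(.st(i_this, -1), .st(idx[[sname(pnew)]], 1),
                           .st(free_sp, 1)))
        if (m %in% names(.occ_phospho)) {
          pph <- p
          pph[match(m, pph)] <- .occ_phospho[[m]]
          .add_reaction(rx, i_this, 0L, "q", cnt,
                        list(.st(i_this, -1), .st(idx[[sname(pph)]], 1)))
        }
      }
    }
  } else {
    ## Distinct sites: left occupant bound via GP130 (k.a rates), right via
    ## IL-27Ralpha (k.b rates).  No statistical factors.
    states <- c(list(c("E", "E")), .heterodimer_pairs)
    sname <- function(p) .dimer_species_name(core, p[1], p[2])
    for (p in states) {
      i_this <- idx[[sname(p)]]
      for (side in 1:2) {
        site <- if (side == 1) "a" else "b"
        occ <- p[side]
        if (occ == "E") {
          for (s in c("S1", "S3")) {
            pnew <- p; pnew[side] <- s
            .add_reaction(rx, i_this, idx[[s]], .occ_on_rate[[site]][[s]], 1,
                          list(.st(i_this, -1), .st(idx[[s]], -1),
                               .st(idx[[sname(pnew)]], 1)))
          }
        } else {
          pnew <- p; pnew[side] <- "E"
          free_sp <- idx[[.occ_free_species[[occ]]]]
          .add_reaction(rx, i_this, 0L, .occ_off_rate[[site]][[occ]], 1,
                        list(.st(i_this, -1), .st(idx[[sname(pnew)]], 1),
                             .st(free_sp, 1)))
          if (occ %in% names(.occ_phospho)) {
            pph <- p; pph[side] <- .occ_phospho[[occ]]
            .add_reaction(rx, i_this, 0L, "q", 1,
                          list(.st(i_this, -1), .st(idx[[sname(pph)]], 1)))
          }
        }
      }
    }
  }

  ## free pSTAT dephosphorylation
  .add_reaction(rx, idx["pS1"], 0L, "d1", 1,
                list(.st(idx["pS1"], -1), .st(idx["S1"], 1)))
  .add_reaction(rx, idx["pS3"], 0L, "d3", 1,
                list(.st(idx["pS3"], -1), .st(idx["S3"], 1)))

  tmpl <- list(
    n_species = nrow(reg),
    i1 = rx$i1, i2 = rx$i2, rate = rx$rate, factor = rx$factor,
    st_sp = rx$st_sp, st_rx = rx$st_rx, st_co = rx$st_co,
    receptor_idx = which(reg$receptor),
    pS1_idx = idx[["pS1"]], pS3_idx = idx[["pS3"]]
  )
  .statkin_cache[[key]] <- tmpl
  tmpl
}

#' Instantiate the mass-action network of a model variant
#'
#' Binds numeric rate values into the reaction template of a model
#' topology.  Mostly an internal workhorse; exposed because the reaction
#' list is useful for inspection and for independent verification of the
#' right-hand side.
#'
#' @param spec A [model_spec()].
#' @param rates A [kinetic_rates()] vector (variant overrides are applied).
#' @return List with reaction arrays (\code{i1}, \code{i2}, effective rate
#'   constants \code{k} = statistical factor times rate), stoichiometry
#'   triplets, internalization indices/rate/mode, and species count.
#' @export
build_network <- function(spec, rates) {
  rates <- apply_variant_rates(spec, rates)
  tmpl <- .build_template(spec)
  j <- if (spec$cytokine == "HYPIL6") "6" else "27"
  int_rate <- if (spec$hypothesis == "H1") {
    rates[[paste0("beta", j)]]
  } else {
    rates[[paste0("gamma", j)]]
  }
  list(
    n_species = tmpl$n_species,
    i1 = tmpl$i1, i2 = tmpl$i2,
    k = tmpl$factor * unname(unlist(rates)[tmpl$rate]),
    rate_names = tmpl$rate,
    st_sp = tmpl$st_sp, st_rx = tmpl$st_rx, st_co = tmpl$st_co,
    receptor_idx = tmpl$receptor_idx,
    int_rate = int_rate,
    int_mode = if (spec$hypothesis == "H1") 1L else 2L,
    pS1_idx = tmpl$pS1_idx, pS3_idx = tmpl$pS3_idx
  )
}

#' Mass-action right-hand side
#'
#' Evaluates the time derivative (nM/s) of a state vector under a model
#' variant: the sum of mass-action reaction fluxes plus the removal of
#' every receptor-containing species by internalization (first order under
#' H1; proportional to free pSTAT1 + pSTAT3 under H2).  This is the
#' reference R implementation; [integrate_model()] uses an equivalent
#' compiled routine.
#'
#' @param spec A [model_spec()].
#' @param rates A [kinetic_rates()] vector.
#' @param state Numeric state vector aligned to the registry (nM).
#' @param network Optional prebuilt [build_network()] result (overrides
#'   \code{spec}/\code{rates}).
#' @return Numeric derivative vector (nM/s) aligned to the registry.
#' @export
rhs <- function(spec, rates, state, network = NULL) {
  net <- if (is.null(network)) build_network(spec, rates) else network
  if (length(state) != net$n_species) {
    stop("state length ", length(state), " does not match registry size ",
         net$n_species, call. = FALSE)
  }
  if (any(state < -1e-6)) {
    stop("state has negative entries beyond tolerance", call. = FALSE)
  }
  y2 <- c(state, 1)          # virtual species for unary reactions
  i2 <- ifelse(net$i2 == 0L, net$n_species + 1L, net$i2)
  v <- net$k * y2[net$i1] * y2[i2]
  dy <- numeric(net$n_species)
  acc <- tapply(net$st_co * v[net$st_rx], net$st_sp, sum)
  dy[as.integer(names(acc))] <- acc
  rint <- net$int_rate
  if (net$int_mode == 2L) {
    rint <- rint * (state[net$pS1_idx] + state[net$pS3_idx])
  }
  dy[net$receptor_idx] <- dy[net$receptor_idx] - rint * state[net$receptor_idx]
  unname(dy)
}

## Encode a network into the fixed-length double vector consumed by the
## compiled derivative routine (see src/massaction.c for the layout).
.PARMS_LEN <- 4096L

encode_network_parms <- function(net) {
  nr <- length(net$i1)
  nst <- length(net$st_sp)
  v <- c(net$n_species, nr, nst,
         net$i1, net$i2, net$k,
         net$st_sp, net$st_rx, net$st_co,
         length(net$receptor_idx), net$receptor_idx,
         net$int_rate, net$int_mode, net$pS1_idx, net$pS3_idx)
  if (length(v) > .PARMS_LEN) stop("network too large for parameter buffer")
  c(v, numeric(.PARMS_LEN - length(v)))
}
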