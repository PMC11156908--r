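#' @useDynLib picoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qchisq rnorm runif setNames lm coef vcov dbinom sd var
#' @importFrom utils read.delim write.table head tail
NULL

COMPARTMENTS <- c(h = "chloroplast", c = "cytosol", m = "mitochondria",
                  x = "external", ext = "external")

species_compartment <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(NA_character_)
  suf <- parts[length(parts)]
  if (suf %in% names(COMPARTMENTS)) unname(COMPARTMENTS[suf]) else NA_character_
}

is_external_id <- function(id) {
  cmp <- vapply(id, species_compartment, character(1))
  !is.na(cmp) & cmp == "external"
}

parse_term <- function(txt, row_id) {
  m <- regexec("^\\s*([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?([A-Za-z][A-Za-z0-9_.]*)\\s*(\\(([a-z]+)\\))?\\s*$",
               txt)
  g <- regmatches(txt, m)[[1]]
  if (length(g) == 0)
    stop(sprintf("reaction '%s': cannot parse term '%s'", row_id, txt))
  coef <- if (nzchar(trimws(g[2]))) as.numeric(trimws(g[2])) else 1
  atoms <- if (nzchar(g[5])) strsplit(g[5], "")[[1]] else NULL
  list(species = g[3], coef = coef, atoms = atoms)
}

parse_equation <- function(eq, row_id) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop(sprintf("reaction '%s': malformed equation '%s'", row_id, eq))
  if (length(sides) == 1) sides <- c(sides, "")
  split_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, "+", fixed = TRUE)[[1]], parse_term, row_id = row_id)
  }
  list(lhs = split_side(sides[1]), rhs = split_side(sides[2]))
}

#' Parse a reaction-network table with carbon atom transitions
#'
#' Reads a delimited table (columns `id`, `equation`, `reversible`, and
#' optionally `pathway`, `notes`) describing a compartmentalized metabolic
#' network. Atom transitions use lowercase letters in parentheses, 1-based
#' left to right, e.g. `"OAA.c (abcd) -> PEP.c (abc) + CO2.c (d)"`.
#' Compartments are species suffixes (`.h` chloroplast, `.c` cytosol,
#' `.m` mitochondria); species with the `.ext` suffix are external
#' (unbalanced) pools such as the labeled inorganic-carbon source.
#' Sink reactions have an empty right-hand side and may carry numeric
#' coefficients without atom maps.
#'
#' Every reaction is checked for atom balance (reactant and product carbon
#' label multisets must agree) and for consistency of inferred species
#' carbon counts across reactions.
#'
#' @param table path to a TSV/CSV file, or a data.frame with the columns
#'   above.
#' @param symmetric character vector of species ids treated as rotationally
#'   symmetric molecules (e.g. succinate, fumarate); their label patterns
#'   are scrambled 50/50 on production.
#' @param sep field separator when `table` is a path (default tab).
#' @return an object of class `flux_network`.
#' @export
parse_network <- function(table, symmetric = character(), sep = "\t") {
  if (is.character(table)) {
    tab <- read.delim(table, sep = sep, stringsAsFactors = FALSE,
                      comment.char = "#", strip.white = TRUE)
  } else tab <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("id", "equation", "reversible")
  if (!all(need %in% names(tab)))
    stop("network table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicated reaction id: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  if (!"pathway" %in% names(tab)) tab$pathway <- ""
  if (!"notes" %in% names(tab)) tab$notes <- ""

  reactions <- vector("list", nrow(tab))
  carbons <- list()   # species -> inferred carbon count
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    eq <- parse_equation(tab$equation[i], id)
    # atom-map validation
    for (side in c("lhs", "rhs")) {
      atoms <- unlist(lapply(eq[[side]], `[[`, "atoms"))
      if (anyDuplicated(atoms))
        stop(sprintf("reaction '%s': atom label used twice on one side (%s)",
                     id, paste(atoms[duplicated(atoms)], collapse = ",")))
    }
    la <- sort(unlist(lapply(eq$lhs, `[[`, "atoms")))
    ra <- sort(unlist(lapply(eq$rhs, `[[`, "atoms")))
    if (length(eq$rhs) > 0 && (length(la) > 0 || length(ra) > 0)) {
      if (!identical(la, ra))
        stop(sprintf("reaction '%s': atom maps unbalanced (lhs '%s' vs rhs '%s')",
                     id, paste(la, collapse = ""), paste(ra, collapse = "")))
      mapped <- vapply(c(eq$lhs, eq$rhs), function(t) !is.null(t$atoms), logical(1))
      if (!all(mapped))
        stop(sprintf("reaction '%s': mixed mapped and unmapped species", id))
    }
    for (t in c(eq$lhs, eq$rhs)) {
      if (!is.null(t$atoms)) {
        n <- length(t$atoms)
        if (!is.null(carbons[[t$species]]) && carbons[[t$species]] != n)
          stop(sprintf("reaction '%s': carbon-count mismatch for species '%s' (%d vs %d)",
                       id, t$species, carbons[[t$species]], n))
        carbons[[t$species]] <- n
      }
    }
    reactions[[i]] <- list(id = id, lhs = eq$lhs, rhs = eq$rhs,
                           reversible = isTRUE(as.logical(tab$reversible[i])),
                           pathway = tab$pathway[i], notes = tab$notes[i])
  }

  sp_ids <- unique(unlist(lapply(reactions, function(r)
    vapply(c(r$lhs, r$rhs), `[[`, character(1), "species"))))
  species <- data.frame(
    id = sp_ids,
    compartment = vapply(sp_ids, species_compartment, character(1)),
    carbons = vapply(sp_ids, function(s)
      if (s %in% names(carbons)) carbons[[s]] else NA_integer_, numeric(1)),
    external = is_external_id(sp_ids),
    symmetric = sp_ids %in% symmetric,
    stringsAsFactors = FALSE, row.names = NULL
  )

  # classify reactions
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    lsp <- vapply(r$lhs, `[[`, character(1), "species")
    rsp <- if (length(r$rhs)) vapply(r$rhs, `[[`, character(1), "species") else character()
    kind <- if (length(r$rhs) == 0) "sink"
      else if (any(is_external_id(lsp))) "source"
      else if (length(r$lhs) == 1 && length(r$rhs) == 1 &&
               !is.na(species_compartment(lsp)) && !is.na(species_compartment(rsp)) &&
               species_compartment(lsp) != species_compartment(rsp)) "transport"
      else "internal"
    if (kind == "sink" && length(r$rhs) > 0)
      stop(sprintf("reaction '%s': sink reactions consume only", r$id))
    reactions[[i]]$kind <- kind
  }

  net <- structure(list(species = species, reactions = reactions),
                   class = "flux_network")
  net
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d reactions, %d species (%d balanced, %d external)\n",
              length(x$reactions), nrow(x$species),
              sum(!x$species$external), sum(x$species$external)))
  kinds <- table(vapply(x$reactions, `[[`, character(1), "kind"))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, character(1), "id")

balanced_species <- function(net) net$species$id[!net$species$external]

species_carbons <- function(net, id) {
  i <- match(id, net$species$id)
  if (anyNA(i)) stop("unknown species: ", paste(id[is.na(i)], collapse = ", "))
  net$species$carbons[i]
}

#' Stoichiometric matrix over balanced species
#'
#' Signed stoichiometric coefficients with rows = balanced (internal)
#' species and columns = reactions; external species are excluded from
#' balance.
#'
#' @param net a `flux_network`.
#' @return numeric matrix with dimnames (species, reaction ids).
#' @export
stoichiometric_matrix <- function(net) {
  sp <- balanced_species(net)
  rid <- reaction_ids(net)
  S <- matrix(0, length(sp), length(rid), dimnames = list(sp, rid))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (t in r$lhs) if (t$species %in% sp)
      S[t$species, j] <- S[t$species, j] - t$coef
    for (t in r$rhs) if (t$species %in% sp)
      S[t$species, j] <- S[t$species, j] + t$coef
  }
  S
}

#' Particular solution and null-space basis of the steady-state constraint
#'
#' Solves `S v = b` for the metabolic steady state and returns a
#' parameterization `v = v0 + N theta` covering all solutions. Fluxes of
#' reactions named in `fixed` are pinned to the given values and moved to
#' the right-hand side.
#'
#' @param net a `flux_network`.
#' @param b right-hand side per balanced species (default zero, i.e. sinks
#'   are explicit reactions in the network); a named vector.
#' @param fixed named numeric vector of fixed reaction fluxes.
#' @param tol consistency tolerance for `||S v0 - b||`.
#' @return list with `v0` (full-length particular solution), `N` (matrix,
#'   rows = all reactions, orthonormal columns spanning the free
#'   directions), `free_dim`, and `reconstruct(theta)`.
#' @export
free_flux_basis <- function(net, b = NULL, fixed = NULL, tol = 1e-8) {
  S <- stoichiometric_matrix(net)
  rid <- colnames(S)
  bb <- setNames(numeric(nrow(S)), rownames(S))
  if (!is.null(b)) bb[names(b)] <- b
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% rid)) stop("fixed references unknown reactions")
    bb <- bb - as.vector(S[, names(fixed), drop = FALSE] %*% fixed)
    free <- setdiff(rid, names(fixed))
  } else free <- rid
  Sf <- S[, free, drop = FALSE]
  qrS <- qr(Sf)
  v_free <- qr.coef(qrS, bb)
  v_free[is.na(v_free)] <- 0
  resid <- Sf %*% v_free - bb
  if (max(abs(resid)) > tol) {
    bad <- rownames(S)[abs(resid) > tol]
    stop("infeasible demands; violated species balance: ",
         paste(bad, collapse = ", "))
  }
  N_free <- MASS::Null(t(Sf))
  if (is.null(dim(N_free))) N_free <- matrix(N_free, ncol = 0, nrow = length(free))
  v0 <- setNames(numeric(length(rid)), rid)
  v0[free] <- v_free
  if (!is.null(fixed)) v0[names(fixed)] <- fixed
  N <- matrix(0, length(rid), ncol(N_free), dimnames = list(rid, NULL))
  if (ncol(N_free)) N[free, ] <- N_free
  reconstruct <- function(theta) {
    stopifnot(length(theta) == ncol(N))
    v0 + as.vector(N %*% theta)
  }
  list(v0 = v0, N = N, free_dim = ncol(N), reconstruct = reconstruct)
}

#' Attach biomass sink reactions from a precursor demand vector
#'
#' Adds one consuming sink reaction per macromolecule class, with
#' stoichiometric coefficients in mmol precursor per gDW biomass; at a
#' specific growth rate `mu` (1/h) each sink carries flux `mu`, giving
#' demands in mmol gDW^-1 h^-1.
#'
#' @param net a `flux_network`.
#' @param demands data.frame with columns `class`, `species`,
#'   `mmol_per_gDW`.
#' @param growth_rate specific growth rate (1/h), stored as the default
#'   sink flux (attribute `sink_flux`).
#' @return a `flux_network` with `sink_<class>` reactions appended.
#' @export
attach_biomass_sink <- function(net, demands, growth_rate = NA_real_) {
  stopifnot(all(c("class", "species", "mmol_per_gDW") %in% names(demands)))
  unknown <- setdiff(demands$species, net$species$id)
  if (length(unknown))
    stop("demand on unknown species: ", paste(unknown, collapse = ", "))
  for (cls in unique(demands$class)) {
    d <- demands[demands$class == cls & demands$mmol_per_gDW > 0, , drop = FALSE]
    if (!nrow(d)) next
    lhs <- lapply(seq_len(nrow(d)), function(k)
      list(species = d$species[k], coef = d$mmol_per_gDW[k], atoms = NULL))
    rxn <- list(id = paste0("sink_", cls), lhs = lhs, rhs = list(),
                reversible = FALSE, pathway = "biomass", notes = "",
                kind = "sink")
    if (rxn$id %in% reaction_ids(net))
      stop("duplicated reaction id: ", rxn$id)
    net$reactions[[length(net$reactions) + 1]] <- rxn
  }
  attr(net, "sink_flux") <- growth_rate
  net
}

#' Validate a network and report atom balance
#'
#' @param net a `flux_network`.
#' @param check_feasibility also verify that a strictly positive
#'   steady-state flux solution exists (all irreversible reactions above
#'   `eps`).
#' @param eps positivity margin for the feasibility check.
#' @return list with `ok`, `messages`, and (if requested) `feasible` and a
#'   witness flux vector.
#' @export
validate_network <- function(net, check_feasibility = FALSE, eps = 1e-3) {
  msgs <- character()
  for (r in net$reactions) {
    la <- sort(unlist(lapply(r$lhs, `[[`, "atoms")))
    ra <- sort(unlist(lapply(r$rhs, `[[`, "atoms")))
    if (r$kind %in% c("internal", "transport", "source") &&
        !identical(la, ra))
      msgs <- c(msgs, sprintf("reaction '%s': atom multiset mismatch", r$id))
  }
  out <- list(ok = length(msgs) == 0, messages = msgs)
  if (check_feasibility) {
    w <- positive_flux_witness(net, eps = eps)
    out$feasible <- !is.null(w)
    out$witness <- w
    out$ok <- out$ok && out$feasible
  }
  out
}

# Find v with S v = 0 and v_i >= eps on irreversible reactions (and
# |v_i| >= eps on reversible ones not required). Returns NULL if none found.
positive_flux_witness <- function(net, eps = 1e-3, box = 50) {
  basis <- free_flux_basis(net)
  if (basis$free_dim == 0) return(NULL)
  rid <- reaction_ids(net)
  irrev <- !vapply(net$reactions, `[[`, logical(1), "reversible")
  obj <- function(theta) {
    v <- basis$reconstruct(theta)
    sum(pmax(eps - v[irrev], 0)^2) + 1e-6 * sum(theta^2) / length(theta)
  }
  best <- NULL
  set.seed(1)
  for (k in 1:30) {
    th0 <- runif(basis$free_dim, -2, 2) * k / 6
    fit <- stats::nlminb(th0, obj, lower = -box, upper = box)
    v <- basis$reconstruct(fit$par)
    if (all(v[irrev] >= eps * 0.999)) { best <- v; break }
  }
  best
}

#' Write a network back to its delimited table format
#'
#' Round-trip counterpart of [parse_network()].
#' @param net a `flux_network`.
#' @param path output file path (TSV).
#' @export
write_network <- function(net, path) {
  fmt_term <- function(t) {
    s <- if (t$coef != 1) paste0(format(t$coef), " ", t$species) else t$species
    if (!is.null(t$atoms)) s <- paste0(s, " (", paste(t$atoms, collapse = ""), ")")
    s
  }
  rows <- lapply(net$reactions, function(r) {
    lhs <- paste(vapply(r$lhs, fmt_term, character(1)), collapse = " + ")
    rhs <- paste(vapply(r$rhs, fmt_term, character(1)), collapse = " + ")
    data.frame(id = r$id, equation = trimws(paste(lhs, "->", rhs)),
               reversible = r$reversible, pathway = r$pathway,
               notes = r$notes, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a bundled reaction network
#'
#' @param name one of `"pcel"` (reduced ~40-reaction compartmentalized
#'   CBB + glycolysis + incomplete TCA + photorespiration network),
#'   `"tgmini"` (the scenario network used by the synthetic experiment
#'   generator) or `"tgmicro"` (a condensed single-compartment variant for
#'   recovery studies).
#' @return a `flux_network`.
#' @export
load_network <- function(name = c("pcel", "tgmini", "tgmicro")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_network.tsv"),
                      package = "picoflux")
  if (!nzchar(path)) stop("bundled network not found: ", name)
  symmetric <- switch(name,
    pcel = c("SUC.m", "FUM.m"),
    tgmini = c("SUC.c", "FUM.c"),
    tgmicro = character())
  parse_network(path, symmetric = symmetric)
}

# Expand reversible reactions into unidirectional label fluxes and apply
# 50/50 scrambling variants for symmetric product species. Returns a list
# of unidirectional reactions with fields: id, base, dir ("f"/"b"),
# lhs/rhs term lists, weight (product of 0.5 per scrambled product).
expand_unidirectional <- function(net) {
  sym <- net$species$id[net$species$symmetric]
  out <- list()
  add_variants <- function(ur) {
    # scramble symmetric products: each symmetric rhs instance splits into
    # identity and reversed atom order, weight 0.5 each
    variants <- list(ur)
    for (k in seq_along(ur$rhs)) {
      t <- ur$rhs[[k]]
      if (t$species %in% sym && !is.null(t$atoms) && length(t$atoms) > 1) {
        variants <- unlist(lapply(variants, function(v) {
          v2 <- v
          v2$rhs[[k]]$atoms <- rev(v2$rhs[[k]]$atoms)
          v$weight <- v$weight * 0.5
          v2$weight <- v2$weight * 0.5
          list(v, v2)
        }), recursive = FALSE)
      }
    }
    variants
  }
  for (r in net$reactions) {
    fwd <- list(id = paste0(r$id, ".f"), base = r$id, dir = "f",
                lhs = r$lhs, rhs = r$rhs, weight = 1)
    out <- c(out, add_variants(fwd))
    if (r$reversible) {
      bwd <- list(id = paste0(r$id, ".b"), base = r$id, dir = "b",
                  lhs = r$rhs, rhs = r$lhs, weight = 1)
      out <- c(out, add_variants(bwd))
    }
  }
  out
}

# Unidirectional flux values from a net/exchange flux table.
# fluxes: data.frame(id, net, exch). Returns named vector over expanded ids.
unidirectional_fluxes <- function(net, fluxes, urxns = NULL) {
  if (is.null(urxns)) urxns <- expand_unidirectional(net)
  idx <- match(vapply(urxns, `[[`, character(1), "base"), fluxes$id)
  if (anyNA(idx)) stop("flux table missing reactions: ",
                       paste(unique(vapply(urxns, `[[`, character(1), "base")[is.na(idx)]),
                             collapse = ", "))
  net_v <- fluxes$net[idx]
  exch <- if ("exch" %in% names(fluxes)) fluxes$exch[idx] else 0 * net_v
  exch[is.na(exch)] <- 0
  if (any(exch < -1e-12)) stop("exchange fluxes must be nonnegative")
  dirs <- vapply(urxns, `[[`, character(1), "dir")
  v <- ifelse(dirs == "f", pmax(net_v, 0) + exch, pmax(-net_v, 0) + exch)
  setNames(v, vapply(urxns, `[[`, character(1), "id"))
}
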