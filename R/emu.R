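# Elementary metabolite unit (EMU) decomposition.
#
# An EMU is a species plus a sorted set of carbon positions; its mass
# isotopomer distribution (MID) can be balanced independently of the rest
# of the isotopomer space, which is what makes transient label simulation
# tractable. The decomposition walks backwards (demand-driven) from the
# measured fragments, the standard minimal-EMU construction.

emu_key <- function(species, positions) {
  paste0(species, "|", paste(sort(positions), collapse = ","))
}

parse_emu_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  list(species = parts[1], positions = as.integer(strsplit(parts[2], ",")[[1]]))
}

#' Decompose a network into the minimal EMU system for given targets
#'
#' Backward traversal from the measured fragments: for every EMU, each
#' unidirectional reaction producing its species maps the tracked carbon
#' positions back onto reactant carbons, yielding either a simple transfer
#' (one source EMU) or a convolution (two or more source EMUs from a
#' condensation). Symmetric species contribute 50/50 scrambled variants.
#'
#' @param net a `flux_network`.
#' @param targets character vector; either species ids (full-molecule
#'   fragments) or explicit EMU keys `"SPECIES|1,2,3"`.
#' @return an object of class `emu_network`: `emus` (data.frame with key,
#'   species, size, ordered by size then key), `reactions` (list of
#'   producer terms: product key, source keys, unidirectional reaction id,
#'   scrambling weight), and `urxns` (the expanded unidirectional
#'   reactions).
#' @export
decompose_emu <- function(net, targets) {
  urxns <- expand_unidirectional(net)
  target_keys <- vapply(targets, function(t) {
    if (grepl("|", t, fixed = TRUE)) {
      p <- parse_emu_key(t)
      emu_key(p$species, p$positions)
    } else {
      nc <- species_carbons(net, t)
      if (is.na(nc)) stop("target species lacks an atom map: ", t)
      emu_key(t, seq_len(nc))
    }
  }, character(1))

  ext <- net$species$id[net$species$external]
  seen <- character()
  queue <- unique(target_keys)
  emu_rxns <- list()

  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    e <- parse_emu_key(key)
    if (e$species %in% ext) next   # source pool, prescribed MID
    producers <- list()
    for (ur in urxns) {
      for (t in ur$rhs) {
        if (t$species != e$species) next
        if (is.null(t$atoms))
          stop("target species lacks an atom map: ", e$species)
        letters_needed <- t$atoms[e$positions]
        # group needed letters by source (lhs) instance
        srcs <- list()
        for (lt in ur$lhs) {
          hit <- which(lt$atoms %in% letters_needed)
          if (length(hit))
            srcs[[length(srcs) + 1]] <- emu_key(lt$species, hit)
        }
        n_found <- sum(vapply(srcs, function(k) length(parse_emu_key(k)$positions),
                              numeric(1)))
        if (n_found != length(letters_needed))
          stop(sprintf("EMU %s: producing reaction %s does not account for all carbons",
                       key, ur$id))
        producers[[length(producers) + 1]] <-
          list(product = key, sources = unlist(srcs), urxn = ur$id,
               weight = ur$weight)
        queue <- c(queue, setdiff(unlist(srcs), seen))
      }
    }
    if (!length(producers))
      stop("unreachable EMU (no producing reaction): ", key)
    emu_rxns <- c(emu_rxns, producers)
  }

  internal <- seen[!vapply(seen, function(k) parse_emu_key(k)$species %in% ext,
                           logical(1))]
  sizes <- vapply(internal, function(k) length(parse_emu_key(k)$positions),
                  numeric(1))
  ord <- order(sizes, internal)
  emus <- data.frame(key = internal[ord],
                     species = vapply(internal[ord], function(k)
                       parse_emu_key(k)$species, character(1)),
                     size = sizes[ord],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(emus = emus, reactions = emu_rxns, urxns = urxns,
                 targets = target_keys, cache = new.env(parent = emptyenv())),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network> %d EMUs (sizes %s), %d EMU reactions, %d targets\n",
              nrow(x$emus),
              paste(range(x$emus$size), collapse = "-"),
              length(x$reactions), length(x$targets)))
  invisible(x)
}

#' Edge-list dump of an EMU network (debugging aid)
#' @param emunet an `emu_network`.
#' @return data.frame with columns product, source, urxn, weight (one row
#'   per product-source edge).
#' @export
emu_graph <- function(emunet) {
  do.call(rbind, lapply(emunet$reactions, function(r)
    data.frame(product = r$product, source = r$sources, urxn = r$urxn,
               weight = r$weight, stringsAsFactors = FALSE)))
}

#' Convolve two mass isotopomer distributions
#'
#' The MID of a fragment assembled from two independent parts is the
#' discrete convolution of the part MIDs.
#'
#' @param mid_a,mid_b numeric mole-fraction vectors (M+0 ... M+n), each
#'   summing to 1.
#' @return numeric vector of length `length(mid_a) + length(mid_b) - 1`.
#' @export
convolve_mid <- function(mid_a, mid_b) {
  if (any(mid_a < 0) || any(mid_b < 0)) stop("negative MID entries")
  if (abs(sum(mid_a) - 1) > 1e-9 || abs(sum(mid_b) - 1) > 1e-9)
    stop("MIDs must sum to 1")
  na <- length(mid_a); nb <- length(mid_b)
  out <- numeric(na + nb - 1)
  for (i in seq_len(na)) out[i:(i + nb - 1)] <- out[i:(i + nb - 1)] + mid_a[i] * mid_b
  out
}
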