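# Circular (Morgan-style) count fingerprints and reaction-difference
# fingerprints.
#
# Implemented in-package on the molecular graph: iterative neighbourhood
# hashing from per-atom invariants (element, heavy degree, implicit H count,
# formal charge), one count per (atom, radius) environment, folded modulo the
# fingerprint length. An atom stops emitting new environments once its
# neighbourhood stops growing, so e.g. methane populates exactly one
# environment. Counts (not bits) are kept so that reaction-difference
# fingerprints retain multiplicities. Hash identity is deterministic and
# depends only on the molecular graph, hence is invariant under SMILES
# respelling (canonicalization happens upstream in OpenBabel).

.hash_prime <- 2147483647  # 2^31 - 1; products stay exact in doubles

hash_fold <- function(values) {
  h <- 17
  for (v in values) h <- (h * 31 + v) %% .hash_prime
  h
}

.elem_code <- function(elem) {
  known <- names(.standard_valence)
  idx <- match(elem, known)
  ifelse(is.na(idx), 100 + (utf8ToInt(substr(elem, 1, 1))), idx)
}

atom_invariants <- function(g) {
  deg <- vapply(seq_len(g$n), function(i) {
    sum(g$bonds[, 1] == i) + sum(g$bonds[, 2] == i)
  }, 0)
  vapply(seq_len(g$n), function(i) {
    hash_fold(c(.elem_code(g$elem[i]), deg[i], g$nH[i], g$charge[i] + 10))
  }, 0)
}

# adjacency list with bond orders
adjacency <- function(g) {
  adj <- vector("list", g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  adj
}

circular_environment_ids <- function(g, radius) {
  adj <- adjacency(g)
  ids <- atom_invariants(g)
  # neighbourhood sizes to detect when an environment stops growing
  reach <- lapply(seq_len(g$n), function(i) i)
  out <- ids  # radius-0 environments, one per atom
  for (r in seq_len(radius)) {
    new_ids <- ids
    grown <- logical(g$n)
    new_reach <- reach
    for (i in seq_len(g$n)) {
      nb <- adj[[i]]
      if (is.null(nb)) next
      pairs <- cbind(nb[, 2], ids[nb[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      new_ids[i] <- hash_fold(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
      new_reach[[i]] <- sort(unique(c(reach[[i]], unlist(reach[nb[, 1]]))))
      grown[i] <- length(new_reach[[i]]) > length(reach[[i]])
    }
    out <- c(out, new_ids[grown])
    ids <- new_ids
    reach <- new_reach
    if (!any(grown)) break
  }
  out
}

path_ids <- function(g, max_path = 5) {
  adj <- adjacency(g)
  acode <- vapply(seq_len(g$n),
                  function(i) hash_fold(c(.elem_code(g$elem[i]), g$charge[i] + 10)), 0)
  ids <- numeric(0)
  walk <- function(path_atoms, path_seq) {
    i <- path_atoms[length(path_atoms)]
    nb <- adj[[i]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      j <- nb[k, 1]
      if (j %in% path_atoms) next
      seq2 <- c(path_seq, nb[k, 2], acode[j])
      if (path_atoms[1] < j) {  # count each undirected path once
        ids[length(ids) + 1] <<- min(hash_fold(seq2), hash_fold(rev(seq2)))
      }
      if ((length(seq2) - 1) / 2 < max_path) walk(c(path_atoms, j), seq2)
    }
  }
  for (i in seq_len(g$n)) walk(i, acode[i])
  ids
}

fold_counts <- function(ids, n_bits) {
  counts <- integer(n_bits)
  if (length(ids)) {
    tab <- table(ids %% n_bits)
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  }
  counts
}

#' Circular count fingerprint of a molecule
#'
#' Hashed circular-environment counts at radii 0..`radius` (default 3) folded
#' to `n_bits` buckets. The `"circular_path"` variant appends a second
#' `n_bits`-wide block of hashed linear-path counts (paths of 1-5 bonds),
#' analogous to pairing a circular with a path-based chemical fingerprint.
#'
#' @param smiles A SMILES string.
#' @param radius Maximum environment radius (bonds); default 3.
#' @param n_bits Folded length per block; default 2048.
#' @param variant `"circular"` (default) or `"circular_path"`.
#' @return A `molecule_fp`: an integer count vector of length `n_bits`
#'   (or `2 * n_bits` for the concatenated variant) with attributes `radius`,
#'   `n_bits`, `variant`.
#' @examples
#' fp <- circular_count_fp("CC(=O)O")
#' sum(fp > 0)
#' @export
circular_count_fp <- function(smiles, radius = 3, n_bits = 2048,
                              variant = c("circular", "circular_path")) {
  variant <- match.arg(variant)
  g <- mol_graph(smiles)
  counts <- fold_counts(circular_environment_ids(g, radius), n_bits)
  if (variant == "circular_path") {
    counts <- c(counts, fold_counts(path_ids(g), n_bits))
  }
  structure(counts, radius = radius, n_bits = n_bits, variant = variant,
            class = "molecule_fp")
}

check_fp_compatible <- function(fps) {
  lens <- vapply(fps, length, 0L)
  vars <- vapply(fps, function(f) attr(f, "variant") %||% "circular", "")
  if (length(unique(lens)) != 1 || length(unique(vars)) != 1) {
    abort("Fingerprints differ in length or variant.",
          class = "amidescreen_incompatible_fp")
  }
  invisible(fps)
}

#' Reaction-difference fingerprint
#'
#' The signed count vector `product - sum(reactants)`, element-wise. Adding
#' the summed reactant counts back reconstructs the product fingerprint
#' exactly, and environments unchanged by the reaction cancel, leaving only
#' those created or destroyed around the new bond.
#'
#' @param product_fp A [circular_count_fp()] of the product.
#' @param reactant_fps List of fingerprints of the reactants (same length and
#'   variant).
#' @return A signed integer vector of the same length, class `reaction_fp`.
#' @examples
#' p <- circular_count_fp(amide_product_smiles("CC(=O)O", "CN"))
#' r <- reaction_fingerprint(p, list(circular_count_fp("CC(=O)O"),
#'                                   circular_count_fp("CN")))
#' sum(r != 0) > 0
#' @export
reaction_fingerprint <- function(product_fp, reactant_fps) {
  check_fp_compatible(c(list(product_fp), reactant_fps))
  total <- Reduce(`+`, lapply(reactant_fps, as.integer))
  structure(as.integer(product_fp) - total,
            radius = attr(product_fp, "radius"),
            n_bits = attr(product_fp, "n_bits"),
            variant = attr(product_fp, "variant"),
            class = "reaction_fp")
}
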