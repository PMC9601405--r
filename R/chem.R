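# Molecular graphs from SMILES via OpenBabel (ChemmineOB).
#
# The graph is read from the V2000 molfile text OpenBabel emits (fixed-width
# atom/bond fields plus M CHG lines) rather than from a higher-level
# container: the fields needed here are exactly the heavy-atom elements,
# formal charges and kekulized bond orders. Implicit hydrogen counts are
# derived from standard valences adjusted by formal charge, which is adequate
# for the organic subset handled in amide screening libraries.

.standard_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
                       Cl = 1, Br = 1, I = 1, B = 3)

smiles_to_molfile <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  ln <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(ln) < 4 || is.na(suppressWarnings(as.integer(substr(ln[4], 1, 3))))) {
    abort(paste0("SMILES failed to parse: '", smiles, "'."),
          class = "amidescreen_smiles_parse")
  }
  ln
}

mol_graph <- function(smiles) {
  ln <- smiles_to_molfile(smiles)
  n <- as.integer(substr(ln[4], 1, 3))
  m <- as.integer(substr(ln[4], 4, 6))
  if (n == 0) abort(paste0("SMILES has no atoms: '", smiles, "'."),
                    class = "amidescreen_smiles_parse")
  at <- ln[4 + seq_len(n)]
  elem <- trimws(substr(at, 32, 34))
  code <- suppressWarnings(as.integer(substr(at, 37, 39)))
  code[is.na(code)] <- 0L
  charge <- ifelse(code == 0, 0L, 4L - code)
  bl <- ln[4 + n + seq_len(m)]
  bonds <- if (m > 0) {
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
          as.integer(substr(bl, 7, 9)))
  } else matrix(integer(), 0, 3)
  for (l in grep("^M  CHG", ln, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(l, 7)), "\\s+")[[1]])
    for (j in seq_len(f[1])) charge[f[2 * j]] <- f[2 * j + 1]
  }
  deg <- vapply(seq_len(n),
                function(i) sum(bonds[bonds[, 1] == i | bonds[, 2] == i, 3]), 0)
  val <- unname(.standard_valence[elem])
  val[is.na(val)] <- deg[is.na(val)]  # exotic elements: no implicit H
  nH <- pmax(0, val + charge - deg)
  list(elem = elem, charge = charge, nH = as.integer(nH),
       bonds = bonds, n = n)
}

graph_to_molfile <- function(g) {
  m <- nrow(g$bonds)
  chgcode <- ifelse(g$charge == 0, 0, 4 - g$charge)
  paste(c("", " amidescreen 2D", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n, m),
          sprintf("%10.4f%10.4f%10.4f %-2s 0%3d  0  0  0  0  0  0  0  0  0  0",
                  0, 0, 0, g$elem, chgcode),
          if (m > 0) sprintf("%3d%3d%3d  0  0  0  0",
                             g$bonds[, 1], g$bonds[, 2], g$bonds[, 3]),
          "M  END", "$$$$"),
        collapse = "\n")
}

graph_neighbours <- function(g, i) {
  bd <- g$bonds
  rows <- bd[, 1] == i | bd[, 2] == i
  cbind(other = ifelse(bd[rows, 1] == i, bd[rows, 2], bd[rows, 1]),
        order = bd[rows, 3])
}

#' Canonicalize a SMILES string
#'
#' Round-trips through OpenBabel's canonical SMILES writer, so any two SMILES
#' spellings of one molecule map to the same string.
#'
#' @param smiles A SMILES string.
#' @return The canonical SMILES.
#' @examples
#' canonical_smiles("O=C(C)NC") == canonical_smiles("CC(=O)NC")
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    smiles_to_molfile(s)  # validate first for a clean error
    out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
    sub("\\s.*$", "", out)
  }, character(1), USE.NAMES = FALSE)
}

# carboxylic-acid sites: carbon with a double-bonded O and a neutral OH
find_carboxyl_sites <- function(g) {
  sites <- list()
  for (i in which(g$elem == "C")) {
    nb <- graph_neighbours(g, i)
    os <- nb[g$elem[nb[, "other"]] == "O", , drop = FALSE]
    dbl <- os[os[, "order"] == 2, "other"]
    sgl <- os[os[, "order"] == 1, "other"]
    sgl <- sgl[g$nH[sgl] >= 1 & g$charge[sgl] == 0]
    if (length(dbl) >= 1 && length(sgl) >= 1) {
      sites[[length(sites) + 1]] <- c(carbon = i, hydroxyl = unname(sgl[1]))
    }
  }
  sites
}

# amine sites: neutral N-H with only single bonds, not an amide nitrogen
find_amine_sites <- function(g) {
  hits <- integer()
  for (i in which(g$elem == "N")) {
    if (g$nH[i] < 1 || g$charge[i] != 0) next
    nb <- graph_neighbours(g, i)
    if (nrow(nb) > 0 && any(nb[, "order"] != 1)) next
    amide <- nrow(nb) > 0 && any(vapply(nb[, "other"], function(j) {
      g$elem[j] == "C" && {
        nj <- graph_neighbours(g, j)
        any(g$elem[nj[, "other"]] == "O" & nj[, "order"] == 2)
      }
    }, logical(1)))
    if (!amide) hits <- c(hits, i)
  }
  hits
}

#' Condense an acid and an amine into their amide product
#'
#' Forms the C(=O)-N bond of the amide coupling (losing water) at the graph
#' level and returns the canonical product SMILES. The acid must carry exactly
#' one carboxylic-acid group and the amine exactly one primary or secondary
#' amine N-H site (amide nitrogens and charged nitrogens are not counted);
#' molecules with several reactive sites raise an ambiguity error asking for
#' an explicit product SMILES instead.
#'
#' @param acid_smiles SMILES of the carboxylic acid.
#' @param amine_smiles SMILES of the amine.
#' @return Canonical SMILES of the amide product.
#' @examples
#' amide_product_smiles("CC(=O)O", "CN")        # N-methylacetamide
#' amide_product_smiles("c1ccccc1C(=O)O", "N")  # benzamide
#' @export
amide_product_smiles <- function(acid_smiles, amine_smiles) {
  a <- mol_graph(acid_smiles)
  b <- mol_graph(amine_smiles)
  acid_sites <- find_carboxyl_sites(a)
  if (length(acid_sites) == 0) {
    abort("Acid has no carboxylic-acid group.", class = "amidescreen_no_reactive_site")
  }
  amine_sites <- find_amine_sites(b)
  if (length(amine_sites) == 0) {
    abort("Amine has no primary/secondary amine N-H site.",
          class = "amidescreen_no_reactive_site")
  }
  if (length(acid_sites) > 1 || length(amine_sites) > 1) {
    abort(paste("Multiple reactive sites found; the condensation is ambiguous.",
                "Supply an explicit product SMILES instead."),
          class = "amidescreen_ambiguous_product")
  }
  site <- acid_sites[[1]]
  nidx <- amine_sites[1]
  keep <- setdiff(seq_len(a$n), site[["hydroxyl"]])
  map <- match(seq_len(a$n), keep)
  na_ <- length(keep)
  ab <- a$bonds[a$bonds[, 1] != site[["hydroxyl"]] &
                  a$bonds[, 2] != site[["hydroxyl"]], , drop = FALSE]
  ab[, 1] <- map[ab[, 1]]
  ab[, 2] <- map[ab[, 2]]
  bb <- b$bonds
  if (nrow(bb)) bb[, 1:2] <- bb[, 1:2] + na_
  g <- list(elem = c(a$elem[keep], b$elem),
            charge = c(a$charge[keep], b$charge),
            bonds = rbind(ab, bb, c(map[site[["carbon"]]], nidx + na_, 1L)),
            n = na_ + b$n)
  out <- ChemmineOB::convertFormat("SDF", "CAN", graph_to_molfile(g))
  sub("\\s.*$", "", out)
}
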