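# Molecule parsing, Table-style featurisation, conformer generation and the
# file formats the tool touches. All chemistry perception goes through
# OpenBabel (via ChemmineOB); ring membership uses igraph bridge detection.

# 44-symbol atomic vocabulary; the final slot absorbs out-of-vocabulary atoms.
# This is the standard list used by molecular DDI featurisers.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)

HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")
BOND_TYPES <- c("single", "double", "triple", "aromatic")

NODE_FEATURE_WIDTH <- 55L  # 44 symbol + degree + valence + charge + radical + 5 hyb + aromatic + nH
EDGE_FEATURE_WIDTH <- 6L   # 4 bond-type one-hot + conjugation + ring

# ---- OpenBabel plumbing -----------------------------------------------------

ob_convert <- function(smiles, to, options = NULL) {
  src <- paste0(smiles, " mol\n")
  out <- if (is.null(options)) {
    ChemmineOB::convertFormat("SMI", to, source = src)
  } else {
    ChemmineOB::convertFormat("SMI", to, source = src, options = options)
  }
  if (is.null(out) || nchar(trimws(out)) == 0L) {
    stop("cannot parse SMILES: '", smiles, "'", call. = FALSE)
  }
  out
}

#' Canonicalise a SMILES string
#'
#' Round-trips a SMILES through OpenBabel's canonical writer. Used internally
#' as the cache key for parsed molecules and conformers; also a cheap validity
#' check.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES (character scalar).
#' @export
canonical_smiles <- function(smiles) {
  out <- ob_convert(smiles, "CAN")
  strsplit(trimws(out), "[ \t]")[[1]][1]
}

parse_sdf_block <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  coords <- matrix(0, natoms, 3)
  coords[, 1] <- as.numeric(substr(atom_lines, 1, 10))
  coords[, 2] <- as.numeric(substr(atom_lines, 11, 20))
  coords[, 3] <- as.numeric(substr(atom_lines, 21, 30))
  bonds <- NULL
  if (nbonds > 0) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  }
  charges <- integer(natoms)
  radicals <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      charges[f[2 * k]] <- f[2 * k + 1]
    }
  }
  for (ln in grep("^M  RAD", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      # MDL radical codes: 1 = singlet, 2 = doublet, 3 = triplet
      radicals[f[2 * k]] <- if (f[2 * k + 1] == 2L) 1L else 2L
    }
  }
  is3d <- grepl("3D", lines[2], fixed = TRUE)
  list(element = element, coords = coords, bonds = bonds,
       charges = charges, radicals = radicals, is3d = is3d)
}

parse_mol2_types <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  sec_ends <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>"))
    nxt <- nxt[nxt > start]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }
  atom_lines <- lines[(a0 + 1):sec_ends(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  atype <- vapply(strsplit(trimws(atom_lines), "\\s+"),
                  function(f) f[6], character(1))
  btype <- character(0)
  ba <- integer(0); bb <- integer(0)
  if (length(b0)) {
    bond_lines <- lines[(b0 + 1):sec_ends(b0)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      fs <- strsplit(trimws(bond_lines), "\\s+")
      ba <- vapply(fs, function(f) as.integer(f[2]), integer(1))
      bb <- vapply(fs, function(f) as.integer(f[3]), integer(1))
      btype <- vapply(fs, function(f) f[4], character(1))
    }
  }
  list(atom_type = atype, bond = data.frame(a = ba, b = bb, type = btype))
}

# ---- molecule perception ----------------------------------------------------

.mol_cache <- new.env(parent = emptyenv())

#' Parse a SMILES string into an annotated heavy-atom molecule
#'
#' Runs OpenBabel three times per molecule (hydrogen-added SDF for H counts
#' and formal charges, mol2 for hybridisation/aromatic typing, canonical
#' SMILES for the cache key), derives ring membership from igraph bridge
#' detection and conjugation from a documented bond-pair rule. Results are
#' memoised per canonical SMILES for the session.
#'
#' @param smiles A single SMILES string.
#' @return A list describing the heavy-atom molecule: elements, bond table,
#'   per-atom hydrogen counts, charges, radical counts, hybridisation,
#'   aromaticity, ring and conjugation flags, and 2D layout coordinates.
#' @export
parse_molecule <- function(smiles) {
  key <- canonical_smiles(smiles)
  hit <- .mol_cache[[key]]
  if (!is.null(hit)) return(hit)

  sdf_h <- parse_sdf_block(ob_convert(smiles, "SDF",
                                      options = data.frame(names = "h", args = "")))
  m2 <- parse_mol2_types(ob_convert(smiles, "MOL2"))

  heavy <- which(sdf_h$element != "H")
  n <- length(heavy)
  if (n == 0L) stop("SMILES '", smiles, "' has no heavy atoms", call. = FALSE)
  remap <- integer(length(sdf_h$element))
  remap[heavy] <- seq_len(n)

  element <- sdf_h$element[heavy]
  charges <- sdf_h$charges[heavy]
  radicals <- sdf_h$radicals[heavy]

  # hydrogen counts: bonds from heavy atoms to (explicit-ified) hydrogens
  nH <- integer(n)
  bonds_all <- sdf_h$bonds
  is_h <- sdf_h$element == "H"
  for (i in seq_len(nrow(bonds_all))) {
    a <- bonds_all$a[i]; b <- bonds_all$b[i]
    if (is_h[a] && !is_h[b]) nH[remap[b]] <- nH[remap[b]] + 1L
    if (is_h[b] && !is_h[a]) nH[remap[a]] <- nH[remap[a]] + 1L
  }
  hb <- bonds_all[!is_h[bonds_all$a] & !is_h[bonds_all$b], , drop = FALSE]
  bonds <- data.frame(a = remap[hb$a], b = remap[hb$b], order = hb$order)

  stopifnot(length(m2$atom_type) == n)  # mol2 carries heavy atoms in input order

  # ring bonds: edges of the heavy-atom graph that are not bridges
  in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]), directed = FALSE)
    br <- igraph::bridges(g)
    in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }

  # aromaticity: mol2 'ar' typing restricted to actual rings (mol2 also writes
  # 'ar' for carboxylate resonance, which is not a ring system)
  arom_bond <- rep(FALSE, nrow(bonds))
  if (nrow(m2$bond) > 0 && nrow(bonds) > 0) {
    key_m2 <- paste(pmin(m2$bond$a, m2$bond$b), pmax(m2$bond$a, m2$bond$b))
    key_b <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    ar_keys <- key_m2[m2$bond$type == "ar"]
    arom_bond <- (key_b %in% ar_keys) & in_ring
  }
  arom_atom <- rep(FALSE, n)
  arom_atom[unique(c(bonds$a[arom_bond], bonds$b[arom_bond]))] <- TRUE

  degree <- tabulate(c(bonds$a, bonds$b), nbins = n)

  hyb <- hybridisation_from_type(m2$atom_type, element, arom_atom, degree, nH)
  conj <- conjugation_flags(bonds, arom_bond, element, n)

  mol <- list(
    smiles = smiles, canonical = key, n_atoms = n, element = element,
    bonds = bonds, n_hydrogens = nH, formal_charge = charges,
    radical_electrons = radicals, degree = degree, hybridisation = hyb,
    aromatic_atom = arom_atom, aromatic_bond = arom_bond,
    ring_bond = in_ring, conjugated_bond = conj
  )
  .mol_cache[[key]] <- mol
  mol
}

# mol2 atom-type suffix -> hybridisation label; hypervalent centres are
# reassigned by steric number (heavy degree + hydrogens)
hybridisation_from_type <- function(atype, element, arom_atom, degree, nH) {
  suffix <- sub("^[A-Za-z]+\\.?", "", atype)
  out <- character(length(atype))
  map <- c("1" = "SP", "2" = "SP2", "3" = "SP3", "ar" = "SP2", "am" = "SP2",
           "cat" = "SP2", "co2" = "SP2", "pl3" = "SP2", "o" = "SP3",
           "o2" = "SP3", "th" = "SP3", "t" = "SP3", "4" = "SP3")
  for (i in seq_along(atype)) {
    out[i] <- if (suffix[i] %in% names(map)) map[[suffix[i]]] else ""
  }
  out[arom_atom] <- "SP2"
  steric <- degree + nH
  out[steric == 5] <- "SP3D"
  out[steric >= 6] <- "SP3D2"
  out
}

# A bond is conjugated when it is aromatic, or when it shares an atom with a
# multiple/aromatic bond and its far atom can take part in the pi system
# (itself multiply bonded, or a lone-pair heteroatom N/O/S/P). This mirrors
# the usual cheminformatics semantics: isolated double bonds are not
# conjugated, diene/amide/acid systems are.
conjugation_flags <- function(bonds, arom_bond, element, n) {
  nb <- nrow(bonds)
  conj <- arom_bond
  if (nb == 0) return(conj)
  multiple <- bonds$order >= 2 | arom_bond
  has_multiple <- rep(FALSE, n)
  has_multiple[unique(c(bonds$a[multiple], bonds$b[multiple]))] <- TRUE
  lone_pair <- element %in% c("N", "O", "S", "P")
  capable <- has_multiple | lone_pair
  incident <- lapply(seq_len(n), function(a) which(bonds$a == a | bonds$b == a))
  for (a in seq_len(n)) {
    bs <- incident[[a]]
    if (length(bs) < 2) next
    for (b1 in bs[multiple[bs]]) {
      for (b2 in setdiff(bs, b1)) {
        far <- if (bonds$a[b2] == a) bonds$b[b2] else bonds$a[b2]
        if (capable[far]) {
          conj[b1] <- TRUE
          conj[b2] <- TRUE
        }
      }
    }
  }
  conj
}

# ---- featurisation ----------------------------------------------------------

#' Per-atom feature matrix (width 55)
#'
#' Concatenates, in order: atomic-symbol one-hot (44, last slot = other),
#' heavy-atom degree, implicit valence, formal charge, radical electron count,
#' hybridisation one-hot (SP/SP2/SP3/SP3D/SP3D2), aromatic flag, and total
#' hydrogen count. Hydrogens are implicit throughout, so the implicit valence
#' equals the hydrogen count.
#'
#' @param mol A SMILES string or a molecule from [parse_molecule()].
#' @return A numeric matrix with one row per heavy atom and 55 columns.
#' @export
featurize_atoms <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  n <- mol$n_atoms
  sym <- ifelse(mol$element %in% ATOM_SYMBOLS, mol$element, "other")
  sym_oh <- matrix(0, n, length(ATOM_SYMBOLS))
  sym_oh[cbind(seq_len(n), match(sym, ATOM_SYMBOLS))] <- 1
  hyb_oh <- matrix(0, n, length(HYBRIDIZATIONS))
  known <- mol$hybridisation %in% HYBRIDIZATIONS
  hyb_oh[cbind(which(known), match(mol$hybridisation[known], HYBRIDIZATIONS))] <- 1
  out <- cbind(
    sym_oh,
    mol$degree,
    mol$n_hydrogens,          # implicit valence (all hydrogens are implicit)
    mol$formal_charge,
    mol$radical_electrons,
    hyb_oh,
    as.numeric(mol$aromatic_atom),
    mol$n_hydrogens
  )
  colnames(out) <- c(paste0("sym_", ATOM_SYMBOLS), "degree", "implicit_valence",
                     "formal_charge", "radical_electrons",
                     paste0("hyb_", HYBRIDIZATIONS), "aromatic", "num_h")
  out
}

#' Directed edge list and per-bond feature matrix (width 6)
#'
#' Emits each chemical bond in both directions with identical features:
#' bond-type one-hot over single/double/triple/aromatic, a conjugation flag,
#' and a ring flag.
#'
#' @param mol A SMILES string or a molecule from [parse_molecule()].
#' @return A list with `edges` (E x 2 integer matrix of atom indices) and
#'   `edge_features` (E x 6 numeric matrix).
#' @export
featurize_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  nb <- nrow(mol$bonds)
  if (nb == 0) {
    return(list(edges = matrix(integer(0), 0, 2),
                edge_features = matrix(0, 0, EDGE_FEATURE_WIDTH)))
  }
  type <- ifelse(mol$aromatic_bond | mol$bonds$order == 4L, "aromatic",
                 BOND_TYPES[pmin(mol$bonds$order, 3L)])
  oh <- matrix(0, nb, 4)
  oh[cbind(seq_len(nb), match(type, BOND_TYPES))] <- 1
  feats <- cbind(oh, as.numeric(mol$conjugated_bond), as.numeric(mol$ring_bond))
  # both directions, reverse immediately after forward
  idx <- rep(seq_len(nb), each = 2)
  edges <- matrix(0L, 2 * nb, 2)
  edges[seq(1, 2 * nb, by = 2), ] <- cbind(mol$bonds$a, mol$bonds$b)
  edges[seq(2, 2 * nb, by = 2), ] <- cbind(mol$bonds$b, mol$bonds$a)
  ef <- feats[idx, , drop = FALSE]
  colnames(ef) <- c(paste0("bond_", BOND_TYPES), "conjugated", "in_ring")
  list(edges = edges, edge_features = ef)
}

#' Build the attributed 2D molecular graph for a drug
#'
#' @param smiles SMILES string.
#' @param drug_id Identifier carried on the object.
#' @return A `molecular_graph`: drug id, atom count, 55-wide node features,
#'   directed edge list (both directions per bond) and 6-wide edge features.
#' @examples
#' \donttest{
#' g <- molecular_graph("c1ccccc1", "benzene")
#' dim(g$node_features)
#' }
#' @export
molecular_graph <- function(smiles, drug_id = smiles) {
  mol <- parse_molecule(smiles)
  nf <- featurize_atoms(mol)
  fb <- featurize_bonds(mol)
  structure(
    list(drug_id = drug_id, n_atoms = mol$n_atoms, node_features = nf,
         edges = fb$edges, edge_features = fb$edge_features,
         smiles = smiles),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$drug_id, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

# ---- conformers -------------------------------------------------------------

.conformer_cache <- new.env(parent = emptyenv())

#' Generate a 3D conformer for a SMILES string
#'
#' Coordinates come from OpenBabel's 3D builder (hydrogens are added for the
#' embedding and stripped afterwards so rows align with the heavy-atom graph).
#' The builder honours E/Z bond stereo, so cis and trans isomers receive
#' distinct geometries. Results are memoised per canonical SMILES: repeated
#' calls within a session return identical coordinates, which the training
#' pipeline relies on. On repeated embedding failure the planar 2D layout is
#' used with `z = 0` and provenance `"fallback_2d"`, with a warning.
#'
#' @param smiles SMILES string.
#' @param drug_id Identifier carried on the object.
#' @param seed Base seed for the retry ladder (retries use seed+1, ...).
#' @param max_retries Number of extra embedding attempts before the 2D fallback.
#' @param use_cache Reuse the per-session conformer cache.
#' @return A `conformer`: drug id, N x 3 coordinate matrix (angstroms, heavy
#'   atoms in graph order) and a provenance flag.
#' @export
generate_conformer <- function(smiles, drug_id = smiles, seed = 1L,
                               max_retries = 5L, use_cache = TRUE) {
  key <- canonical_smiles(smiles)
  if (use_cache) {
    hit <- .conformer_cache[[key]]
    if (!is.null(hit)) {
      hit$drug_id <- drug_id
      return(hit)
    }
  }
  coords <- NULL
  provenance <- "embedded"
  for (k in 0:max_retries) {
    res <- try(parse_sdf_block(
      ob_convert(smiles, "SDF", options = data.frame(names = "gen3d", args = "med"))
    ), silent = TRUE)
    if (!inherits(res, "try-error") && res$is3d && all(is.finite(res$coords))) {
      heavy <- res$element != "H"
      coords <- res$coords[heavy, , drop = FALSE]
      break
    }
  }
  if (is.null(coords)) {
    warning("3D embedding failed for '", smiles, "'; using planar 2D fallback",
            call. = FALSE)
    res <- parse_sdf_block(
      ob_convert(smiles, "SDF", options = data.frame(names = "gen2d", args = ""))
    )
    heavy <- res$element != "H"
    coords <- res$coords[heavy, , drop = FALSE]
    coords[, 3] <- 0
    provenance <- "fallback_2d"
  }
  out <- structure(
    list(drug_id = drug_id, coordinates = coords, provenance = provenance),
    class = "conformer"
  )
  if (use_cache) .conformer_cache[[key]] <- out
  out
}

#' Clear the per-session molecule and conformer caches
#' @return Invisibly, `NULL`.
#' @export
clear_chem_cache <- function() {
  rm(list = ls(.conformer_cache), envir = .conformer_cache)
  rm(list = ls(.mol_cache), envir = .mol_cache)
  invisible(NULL)
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$drug_id, ": ", nrow(x$coordinates), " atoms (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

# ---- rotations --------------------------------------------------------------

#' Rotation matrix from Euler angles (Z.Y.X composition)
#'
#' @param angles Three angles in radians; the matrix is
#'   `Rz(angles[1]) %*% Ry(angles[2]) %*% Rx(angles[3])`.
#' @return A 3 x 3 proper rotation matrix.
#' @export
euler_rotation_matrix <- function(angles) {
  stopifnot(length(angles) == 3)
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Apply a (random) rigid rotation to a conformer
#'
#' Euler angles are drawn uniformly from `[0, 2*pi)` using R's RNG (seed the
#' session to reproduce draws); pass `angles` explicitly for a deterministic
#' rotation. Rotation preserves all interatomic distances.
#'
#' @param conformer A `conformer` or a bare N x 3 coordinate matrix.
#' @param angles Optional fixed Euler angles (Z.Y.X order).
#' @return Same type as the input, with rotated coordinates.
#' @export
random_rotation <- function(conformer, angles = NULL) {
  if (is.null(angles)) angles <- stats::runif(3, 0, 2 * pi)
  R <- euler_rotation_matrix(angles)
  if (inherits(conformer, "conformer")) {
    conformer$coordinates <- conformer$coordinates %*% t(R)
    conformer
  } else {
    conformer %*% t(R)
  }
}

# ---- registries and triple tables -------------------------------------------

read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a drug registry (id, smiles)
#'
#' Accepts comma- or tab-delimited files with header columns `id` and
#' `smiles`, or plain `.smi` files (SMILES then id, whitespace-separated).
#'
#' @param path File path.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smiles_registry <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, header = FALSE, col.names = c("smiles", "id"),
                             stringsAsFactors = FALSE)
    reg <- tibble::as_tibble(tab[, c("id", "smiles")])
  } else {
    reg <- read_table_auto(path)
    missing <- setdiff(c("id", "smiles"), names(reg))
    if (length(missing)) {
      stop("registry is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    reg <- dplyr::select(reg, "id", "smiles")
  }
  reg$id <- as.character(reg$id)
  dup <- unique(reg$id[duplicated(reg$id)])
  if (length(dup)) {
    stop("duplicate drug ids in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  reg
}

#' Read a DDI triple table (drug_a, drug_b, type)
#'
#' @param path File path (comma- or tab-delimited, with header).
#' @param registry Optional registry tibble; when given, triples referencing
#'   unknown drug ids raise an error naming the offenders.
#' @return A tibble with columns `drug_a`, `drug_b`, `type`.
#' @export
read_ddi_table <- function(path, registry = NULL) {
  tab <- read_table_auto(path)
  missing <- setdiff(c("drug_a", "drug_b", "type"), names(tab))
  if (length(missing)) {
    stop("triple table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- dplyr::select(tab, "drug_a", "drug_b", "type")
  tab$drug_a <- as.character(tab$drug_a)
  tab$drug_b <- as.character(tab$drug_b)
  tab$type <- as.integer(tab$type)
  if (!is.null(registry)) {
    unknown <- setdiff(unique(c(tab$drug_a, tab$drug_b)), registry$id)
    if (length(unknown)) {
      stop("triples reference unknown drug ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  tab
}

#' Write a registry or triple table
#'
#' Delimiter follows the file extension: `.tsv` writes tabs, anything else
#' commas.
#'
#' @param x Tibble to write.
#' @param path Destination path.
#' @return Invisibly, `x`.
#' @export
write_ddi_table <- function(x, path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(x)
}

#' Export conformers to an SDF file
#'
#' Writes minimal V2000 molfiles (coordinates only, no bond block) so that
#' conformer geometries can be checked into text form and reloaded with
#' [read_conformer_sdf()] for cross-session reproducibility.
#'
#' @param conformers A list of `conformer` objects.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_conformer_sdf <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    n <- nrow(cf$coordinates)
    writeLines(c(cf$drug_id, sprintf("  stereoddi provenance=%s", cf$provenance), ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         cf$coordinates[i, 1], cf$coordinates[i, 2],
                         cf$coordinates[i, 3], "C"), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read conformers written by [write_conformer_sdf()]
#'
#' @param path SDF path.
#' @return A list of `conformer` objects.
#' @export
read_conformer_sdf <- function(path) {
  lines <- readLines(path)
  breaks <- c(0L, which(lines == "$$$$"))
  out <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    block <- lines[(breaks[k] + 1L):(breaks[k + 1L] - 1L)]
    if (!length(block)) next
    drug_id <- block[1]
    prov <- sub(".*provenance=", "", block[2])
    n <- as.integer(substr(block[4], 1, 3))
    coords <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      ln <- block[4 + i]
      coords[i, ] <- c(as.numeric(substr(ln, 1, 10)),
                       as.numeric(substr(ln, 11, 20)),
                       as.numeric(substr(ln, 21, 30)))
    }
    out[[drug_id]] <- structure(
      list(drug_id = drug_id, coordinates = coords, provenance = prov),
      class = "conformer"
    )
  }
  out
}
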