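#' Descriptor families available from the built-in engine
#'
#' Six families cover the usual QSAR blocks: continuous
#' physicochemical properties, constitutional counts, graph-topological
#' indices, and three binary fingerprint families (curated substructure
#' keys, path-based FP2 bits, MACCS-style keys). Columns are prefixed by
#' family so provenance is recoverable from the name alone.
#'
#' @return Character vector of family names.
#' @export
descriptor_families <- function() {
  c("physicochemical", "constitutional", "topological",
    "substructure_fp", "path_fp", "maccs_like_fp")
}

family_prefix <- c(
  physicochemical = "phys_", constitutional = "const_",
  topological = "topo_", substructure_fp = "subfp_",
  path_fp = "pathfp_", maccs_like_fp = "maccs_")

# Curated SMARTS substructure keys. Deliberately compact and
# interpretable: halogens, common polar groups, small alkyl branches and
# the heteroaromatic cores relevant to kinase-inhibitor chemistry.
substructure_keys <- function() {
  c(F        = "[F]",
    Cl       = "[Cl]",
    Br       = "[Br]",
    I        = "[I]",
    CF3      = "FC(F)F",
    OMe      = "[CH3][OX2]",
    NH2      = "[NX3;H2]",
    NHsec    = "[NX3;H1;!$(NC=O)]",
    OH       = "[OX2H]",
    nitrile  = "C#N",
    nitro    = "[NX3](~[OX1])~[OX1]",
    carbonyl = "[CX3]=[OX1]",
    amide    = "[CX3](=[OX1])[NX3]",
    ether    = "[OX2]([#6])[#6]",
    thio     = "[SX2]",
    sulfonyl = "[SX4](=[OX1])=[OX1]",
    benzene  = "c1ccccc1",
    pyrimidine = "c1ccncn1",
    azole    = "[nX2]1cc[cX3]n1",
    aromN    = "[nX2]",
    ethyl    = "[CH2][CH3]",
    branchC  = "[CX4H]([#6])([#6])[#6]")
}

# Parse SMILES into an SDFset with compound ids as cids; hard error
# names the offending compounds.
parse_smiles_set <- function(compounds) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(
      setNames(compounds$smiles, compounds$compound_id))),
    error = function(e) abort(sprintf("SMILES parsing failed: %s",
                                      conditionMessage(e))))
  ChemmineR::cid(sdf) <- compounds$compound_id
  # validSDF() rejects bond-free molecules (e.g. methane); a molecule is
  # acceptable here when it parsed to at least one atom
  ok <- vapply(ChemmineR::SDFset2SDF(sdf), function(m)
    isTRUE(tryCatch(nrow(ChemmineR::atomblock(m)) > 0,
                    error = function(e) FALSE)), logical(1))
  if (!all(ok)) {
    abort(sprintf("Structure(s) failed to parse: %s",
                  paste(compounds$compound_id[!ok], collapse = ", ")))
  }
  sdf
}

#' Compute a descriptor matrix for a compound set
#'
#' Generates the requested descriptor families from SMILES via
#' OpenBabel (properties, FP2 and MACCS fingerprints, SMARTS
#' substructure keys) and the molecular graph (topological indices).
#' Output is deterministic for fixed input. Constant columns are
#' retained; pruning them is the selection stage's job.
#'
#' @param compounds Compound tibble with `compound_id` and `smiles`.
#' @param families Subset of [descriptor_families()].
#' @return Tibble: `compound_id` plus one numeric column per descriptor,
#'   names prefixed by family (`phys_`, `const_`, `topo_`, `subfp_`,
#'   `pathfp_`, `maccs_`). Fingerprint families contain only 0/1.
#' @export
compute_descriptors <- function(compounds, families = descriptor_families()) {
  if (nrow(compounds) == 0) abort("Empty compound set.")
  bad <- setdiff(families, descriptor_families())
  if (length(bad) > 0) {
    abort(sprintf("Unknown descriptor family: %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(compounds$compound_id)) {
    abort("compound_id values must be unique.")
  }
  sdf <- parse_smiles_set(compounds)

  blocks <- list(tibble(compound_id = compounds$compound_id))
  if ("constitutional" %in% families) {
    blocks <- c(blocks, list(constitutional_block(sdf)))
  }
  if ("topological" %in% families) {
    blocks <- c(blocks, list(topological_block(sdf)))
  }
  ob_fams <- intersect(families, c("physicochemical", "substructure_fp",
                                   "path_fp", "maccs_like_fp"))
  if (length(ob_fams) > 0) {
    blocks <- c(blocks, openbabel_blocks(compounds$smiles, ob_fams))
  }
  out <- bind_cols(blocks)
  out <- out[c("compound_id",
               unlist(map(families, function(f)
                 feature_names(out)[startsWith(feature_names(out),
                                               family_prefix[[f]])])))]
  check_descriptor_tbl(out)
  out
}

# One OpenBabel pass per molecule computes every OB-derived family:
# properties, curated SMARTS keys, and the FP2/MACCS fingerprints.
openbabel_blocks <- function(smiles, families) {
  keys <- substructure_keys()
  per_mol <- ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"),
    function(mol) {
      mol <- list(mol)
      out <- list()
      if ("physicochemical" %in% families) {
        out$phys <- ChemmineOB::prop_OB(mol)
      }
      if ("substructure_fp" %in% families) {
        out$subfp <- vapply(keys, function(smarts) as.numeric(
          ChemmineOB::smartsSearch_OB(mol, smarts,
                                      uniqueMatches = FALSE) > 0),
          numeric(1))
      }
      if ("path_fp" %in% families) {
        out$pathfp <- as.numeric(ChemmineOB::fingerprint_OB(mol, "FP2"))
      }
      if ("maccs_like_fp" %in% families) {
        out$maccs <- as.numeric(ChemmineOB::fingerprint_OB(mol, "MACCS"))
      }
      out
    })
  blocks <- list()
  if ("physicochemical" %in% families) {
    p <- bind_rows(map(per_mol, function(m) as_tibble(m$phys)))
    keep <- intersect(c("MW", "logP", "TPSA", "HBA1", "HBA2", "HBD",
                        "MR", "nF"), names(p))
    p <- p[keep]
    names(p) <- paste0("phys_", names(p))
    blocks <- c(blocks, list(p))
  }
  if ("substructure_fp" %in% families) {
    s <- as_tibble(do.call(rbind, map(per_mol, "subfp")),
                   .name_repair = "minimal")
    names(s) <- paste0("subfp_", names(keys))
    blocks <- c(blocks, list(s))
  }
  if ("path_fp" %in% families) {
    f <- as_tibble(do.call(rbind, map(per_mol, "pathfp")),
                   .name_repair = "minimal")
    names(f) <- sprintf("pathfp_%04d", seq_len(ncol(f)))
    blocks <- c(blocks, list(f))
  }
  if ("maccs_like_fp" %in% families) {
    f <- as_tibble(do.call(rbind, map(per_mol, "maccs")),
                   .name_repair = "minimal")
    names(f) <- sprintf("maccs_%04d", seq_len(ncol(f)))
    blocks <- c(blocks, list(f))
  }
  blocks
}

# Bond table, tolerating bond-free molecules (single heavy atom).
safe_bondblock <- function(m) {
  bb <- tryCatch(ChemmineR::bondblock(m), error = function(e) NULL)
  if (is.null(bb) || length(bb) == 0 || is.null(dim(bb))) {
    bb <- matrix(integer(0), nrow = 0, ncol = 3)
  }
  # bond-free molecules parse with a placeholder all-zero bond row
  bb[bb[, 1] >= 1 & bb[, 2] >= 1, , drop = FALSE]
}

constitutional_block <- function(sdf) {
  counts <- map(ChemmineR::SDFset2SDF(sdf), function(m) {
    ab <- ChemmineR::atomblock(m)
    elems <- gsub("_.*$", "", rownames(ab))
    bb <- safe_bondblock(m)
    c(nHeavy = length(elems),
      nBonds = nrow(bb),
      nC = sum(elems == "C"), nN = sum(elems == "N"),
      nO = sum(elems == "O"), nS = sum(elems == "S"),
      nHal = sum(elems %in% c("F", "Cl", "Br", "I")),
      nRings = nrow(bb) - length(elems) + 1)
  })
  out <- as_tibble(do.call(rbind, counts))
  names(out) <- paste0("const_", names(out))
  out
}

# Topological indices from the heavy-atom molecular graph.
topological_block <- function(sdf) {
  rows <- map(ChemmineR::SDFset2SDF(sdf), function(m) {
    bb <- safe_bondblock(m)
    n <- nrow(ChemmineR::atomblock(m))
    g <- if (nrow(bb) == 0) igraph::make_empty_graph(n, directed = FALSE)
         else igraph::graph_from_edgelist(
           cbind(as.integer(bb[, 1]), as.integer(bb[, 2])), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    d <- igraph::distances(g)
    fin <- d[is.finite(d) & upper.tri(d)]
    deg <- igraph::degree(g)
    ecc <- apply(d, 1, function(r) max(r[is.finite(r)]))
    diam <- max(ecc)
    c(wiener = sum(fin),
      diameter = diam,
      radius = min(ecc),
      petitjean = if (diam > 0) (diam - min(ecc)) / diam else 0,
      zagreb1 = sum(deg^2),
      zagreb2 = if (nrow(bb) > 0)
        sum(deg[as.integer(bb[, 1])] * deg[as.integer(bb[, 2])]) else 0,
      nBranch = sum(deg >= 3),
      meanDist = if (length(fin) > 0) mean(fin) else 0)
  })
  out <- as_tibble(do.call(rbind, rows))
  names(out) <- paste0("topo_", names(out))
  out
}

#' Per-column provenance of a descriptor table
#'
#' @param descriptors Descriptor tibble from [compute_descriptors()]
#'   (possibly with docking columns appended).
#' @return Tibble with columns `column`, `family`, `provenance`
#'   (`chemical_continuous`, `fingerprint_bit` or `docking_energy`).
#' @export
descriptor_provenance <- function(descriptors) {
  cols <- feature_names(descriptors)
  fam <- dplyr::case_when(
    startsWith(cols, "phys_") ~ "physicochemical",
    startsWith(cols, "const_") ~ "constitutional",
    startsWith(cols, "topo_") ~ "topological",
    startsWith(cols, "subfp_") ~ "substructure_fp",
    startsWith(cols, "pathfp_") ~ "path_fp",
    startsWith(cols, "maccs_") ~ "maccs_like_fp",
    startsWith(cols, "dock_") ~ "docking_energy",
    TRUE ~ "unknown")
  tibble(
    column = cols,
    family = fam,
    provenance = dplyr::case_when(
      fam %in% c("substructure_fp", "path_fp", "maccs_like_fp") ~ "fingerprint_bit",
      fam == "docking_energy" ~ "docking_energy",
      TRUE ~ "chemical_continuous"))
}

#' Append docking-energy columns to a descriptor table
#'
#' Adds the seven energy terms as `dock_`-prefixed feature columns,
#' preserving the original column order.
#'
#' @param descriptors Descriptor tibble.
#' @param energies Docking-energy tibble (see [read_docking_energies()]).
#' @param policy `"strict"` (default): every compound must have an
#'   energy record, else error. `"inner"`: keep the intersection with a
#'   warning.
#' @return Descriptor tibble with seven additional `dock_` columns.
#' @export
append_docking_columns <- function(descriptors, energies,
                                   policy = c("strict", "inner")) {
  policy <- match.arg(policy)
  check_descriptor_tbl(descriptors)
  if (anyDuplicated(energies$compound_id)) {
    abort("Duplicate energy record(s) for a compound_id.")
  }
  missing_ids <- setdiff(descriptors$compound_id, energies$compound_id)
  if (length(missing_ids) > 0) {
    if (policy == "strict") {
      abort(sprintf("No docking energies for compound(s): %s",
                    paste(missing_ids, collapse = ", ")))
    }
    warn(sprintf("Dropping %d compound(s) without docking energies.",
                 length(missing_ids)))
  }
  en <- energies |> select("compound_id", dplyr::all_of(docking_energy_terms()))
  names(en) <- c("compound_id", paste0("dock_", docking_energy_terms()))
  out <- descriptors |> inner_join(en, by = "compound_id")
  check_descriptor_tbl(out)
  out
}

#' Screen docking-energy descriptors for pairwise correlation
#'
#' Computes the 7x7 Pearson correlation table of the energy terms and
#' iteratively drops, from each pair with |r| above the cutoff, the
#' member with the larger mean absolute correlation to the remaining
#' terms (a deterministic tie-break that removes the more redundant
#' column). Constant columns have undefined correlations and are dropped
#' up front with a warning.
#'
#' @param energies Docking-energy tibble.
#' @param pairwise_cutoff Absolute-correlation threshold, default 0.8.
#' @return List with elements `retained` (character), `correlations`
#'   (7x7 matrix, NA rows for constant columns) and `dropped` (tibble of
#'   `column`, `reason`, `statistic`).
#' @export
screen_energy_descriptors <- function(energies, pairwise_cutoff = 0.8) {
  if (nrow(energies) < 3) abort("Need at least 3 energy records.")
  terms <- docking_energy_terms()
  m <- as.matrix(energies[terms])
  dropped <- tibble(column = character(), reason = character(),
                    statistic = numeric())

  const <- terms[apply(m, 2, sd) == 0]
  full_cor <- suppressWarnings(cor(m))
  keep <- setdiff(terms, const)
  if (length(const) > 0) {
    warn(sprintf("Constant energy column(s) dropped: %s",
                 paste(const, collapse = ", ")))
    dropped <- bind_rows(dropped, tibble(
      column = const, reason = "constant", statistic = NA_real_))
  }

  repeat {
    cm <- abs(cor(m[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (length(keep) < 2 || max(cm) <= pairwise_cutoff) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(cm[pair, setdiff(keep, pair), drop = FALSE])
    # drop the member more correlated with everything else; tie ->
    # lexicographically later name
    victim <- if (diff(mean_abs) == 0) sort(pair)[2] else pair[which.max(mean_abs)]
    dropped <- bind_rows(dropped, tibble(
      column = victim, reason = sprintf("|r|>%.2f with %s", pairwise_cutoff,
                                        setdiff(pair, victim)),
      statistic = max(cm)))
    keep <- setdiff(keep, victim)
  }
  list(retained = keep, correlations = full_cor, dropped = dropped)
}
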