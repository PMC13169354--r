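#' Standardize a raw SMILES string
#'
#' Runs the curation pipeline applied to every training molecule: parse
#' (dropping stereochemical annotations), select the largest organic fragment
#' (salt/mixture handling), neutralize simple charged groups, and emit the
#' canonical nonisomeric SMILES together with the Bemis-Murcko scaffold,
#' topological complexity key and Morgan fingerprint.
#'
#' A fragment is "organic" when it contains at least one carbon atom; a
#' molecule with no organic fragment is rejected as \code{inorganic}. Ties on
#' fragment size (heavy-atom count) are broken by lexicographic order of the
#' fragment's canonical SMILES. Neutralization protonates anionic N/O/S
#' centres and deprotonates cationic N/O/S centres that carry hydrogens;
#' permanently charged atoms (e.g. quaternary nitrogen) are retained.
#'
#' @param raw_smiles character scalar, possibly multi-fragment, charged and
#'   stereo-annotated.
#' @param fingerprint logical; compute the 2048-bit Morgan fingerprint.
#' @return An object of class \code{standard_mol} (fields
#'   \code{canonical_smiles}, \code{scaffold_smiles}, \code{ring_count},
#'   \code{branch_count}, \code{fingerprint}) or an object of class
#'   \code{mol_rejection} with a \code{reason} of \code{"unparseable"},
#'   \code{"inorganic"} or \code{"empty-after-stripping"}.
#' @examples
#' standardize("C[C@H](N)C(=O)O.Cl")$canonical_smiles
#' standardize("[Na+].[Cl-]")  # rejected as inorganic
#' @export
standardize <- function(raw_smiles, fingerprint = TRUE) {
  mol <- tryCatch(smi_parse(raw_smiles), error = function(e) {
    structure(list(reason = "unparseable", input = raw_smiles,
                   message = conditionMessage(e)), class = "mol_rejection")
  })
  if (inherits(mol, "mol_rejection")) return(mol)
  comp <- .components(mol)
  frag_ids <- unique(comp)
  organic <- vapply(frag_ids, function(cid) any(mol$elem[comp == cid] == "C"), logical(1))
  if (!any(organic))
    return(structure(list(reason = "inorganic", input = raw_smiles),
                     class = "mol_rejection"))
  frag_ids <- frag_ids[organic]
  sizes <- vapply(frag_ids, function(cid) sum(comp == cid), integer(1))
  best <- frag_ids[sizes == max(sizes)]
  if (length(best) > 1) {
    smis <- vapply(best, function(cid) smi_canonical(.subset_mol(mol, which(comp == cid))),
                   character(1))
    best <- best[order(smis)][1]
  }
  mol <- .subset_mol(mol, which(comp == best))
  mol <- .neutralize(mol)
  if (.n_atoms(mol) == 0)
    return(structure(list(reason = "empty-after-stripping", input = raw_smiles),
                     class = "mol_rejection"))
  can <- smi_canonical(mol)
  mol <- smi_parse(can)   # re-parse so stored graph matches the canonical form
  key <- complexity_key(mol)
  structure(list(
    canonical_smiles = can,
    scaffold_smiles  = murcko_scaffold(mol),
    ring_count       = key[["ring_count"]],
    branch_count     = key[["branch_count"]],
    fingerprint      = if (fingerprint) ecfp4(mol) else NULL,
    mol              = mol
  ), class = "standard_mol")
}

#' @export
print.standard_mol <- function(x, ...) {
  cat("<standard_mol>", x$canonical_smiles, "\n")
  cat("  scaffold:", if (nzchar(x$scaffold_smiles)) x$scaffold_smiles else "(acyclic)", "\n")
  cat("  rings:", x$ring_count, " branch points:", x$branch_count, "\n")
  invisible(x)
}

#' @export
print.mol_rejection <- function(x, ...) {
  cat("<rejected SMILES>", x$input, "-", x$reason, "\n")
  invisible(x)
}

.subset_mol <- function(mol, keep) {
  map <- integer(.n_atoms(mol)); map[keep] <- seq_along(keep)
  kb <- which(mol$ba %in% keep & mol$bb %in% keep)
  out <- list(elem = mol$elem[keep], arom = mol$arom[keep],
              charge = mol$charge[keep], hcount = mol$hcount[keep],
              hexplicit = mol$hexplicit[keep],
              ba = map[mol$ba[kb]], bb = map[mol$bb[kb]],
              border = mol$border[kb], barom = mol$barom[kb],
              bdefault = mol$bdefault[kb])
  class(out) <- "mfmol"
  out
}

# protonate/deprotonate simple charged centres where a neutral valence-legal
# form exists; quaternary N (charge +1, no H) and charge-separated groups
# (nitro, N-oxide: an anion bonded to a cation) are kept as-is
.neutralize <- function(mol) {
  adj <- .adjlist(mol)
  for (i in seq_len(.n_atoms(mol))) {
    q <- mol$charge[i]; e <- mol$elem[i]
    if (q == 0L || !(e %in% c("N", "O", "S", "P"))) next
    nbq <- mol$charge[adj[[i]]$atom]
    if (any(sign(nbq) == -sign(q))) next
    if (q == 1L && mol$hcount[i] >= 1L) {       # e.g. [NH3+] -> N
      mol$charge[i] <- 0L
      mol$hcount[i] <- mol$hcount[i] - 1L
      mol$hexplicit[i] <- TRUE
    } else if (q == -1L) {                      # e.g. [O-] -> O(H)
      # only when the neutral atom can carry the extra H
      vals <- .default_valences[[e]]
      bs <- .bondsum(mol)[i]
      if (any(vals >= bs + mol$hcount[i] + 1)) {
        mol$charge[i] <- 0L
        mol$hcount[i] <- mol$hcount[i] + 1L
        mol$hexplicit[i] <- TRUE
      }
    }
  }
  mol
}

.as_mol <- function(x) {
  if (inherits(x, "mfmol")) return(x)
  if (inherits(x, "standard_mol")) return(x$mol)
  if (is.character(x)) return(smi_parse(x))
  stop("invalid_molecule: expected SMILES string, mfmol or standard_mol")
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus the acyclic linkers connecting them; side chains are
#' removed by iteratively deleting terminal atoms, then exocyclic multiple
#' bonds attached to the retained frame are restored (so e.g. a linker
#' carbonyl keeps its oxygen). Returns \code{""} for acyclic molecules.
#'
#' @param mol SMILES string, parsed molecule or \code{standard_mol}.
#' @return Scaffold as canonical SMILES (empty string if acyclic).
#' @examples
#' murcko_scaffold("CCc1ccccc1")  # "c1ccccc1"
#' murcko_scaffold("CCO")         # ""
#' @export
murcko_scaffold <- function(mol) {
  mol <- .as_mol(mol)
  n <- .n_atoms(mol)
  if (.ring_count(mol) == 0) return("")
  keep <- rep(TRUE, n)
  ringb <- .ring_bond_flags(mol)
  in_ring <- rep(FALSE, n)
  in_ring[mol$ba[ringb]] <- TRUE; in_ring[mol$bb[ringb]] <- TRUE
  repeat {
    deg <- numeric(n)
    for (k in seq_len(.n_bonds(mol))) {
      if (keep[mol$ba[k]] && keep[mol$bb[k]]) {
        deg[mol$ba[k]] <- deg[mol$ba[k]] + 1
        deg[mol$bb[k]] <- deg[mol$bb[k]] + 1
      }
    }
    prune <- keep & !in_ring & deg <= 1
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  # restore atoms attached to the frame by a double/triple bond
  repeat {
    added <- FALSE
    for (k in seq_len(.n_bonds(mol))) {
      if (mol$border[k] < 2 || mol$barom[k]) next
      a <- mol$ba[k]; b <- mol$bb[k]
      if (keep[a] && !keep[b]) { keep[b] <- TRUE; added <- TRUE }
      else if (keep[b] && !keep[a]) { keep[a] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  sub <- .subset_mol(mol, which(keep))
  # pruning changes neighbor counts: recompute implicit H for non-bracket atoms
  sub$hcount[!sub$hexplicit] <- NA_integer_
  sub$hcount <- .implicit_h(sub)
  smi_canonical(sub)
}

#' Topological complexity key
#'
#' Ring count (SSSR size, the cyclomatic number) and branching statistic,
#' used to order the training curriculum from simple to complex structures.
#' A branch point is an atom of heavy-atom degree at least 3 that carries at
#' least one acyclic bond; pure ring-fusion atoms (all bonds in rings) are
#' not branch points under the default definition. Set
#' \code{count_ring_fusion = TRUE} to count every atom of degree >= 3.
#'
#' @param mol SMILES string, parsed molecule or \code{standard_mol}.
#' @param count_ring_fusion logical; include ring-fusion atoms.
#' @return Named integer vector \code{c(ring_count=, branch_count=)}.
#' @examples
#' complexity_key("CC(C)(C)c1ccc2ccccc2c1")  # 2 rings, 2 branch points
#' @export
complexity_key <- function(mol, count_ring_fusion = FALSE) {
  mol <- .as_mol(mol)
  deg <- .degree(mol)
  branched <- deg >= 3
  if (!count_ring_fusion && any(branched)) {
    ringb <- .ring_bond_flags(mol)
    has_acyclic <- rep(FALSE, .n_atoms(mol))
    for (k in seq_len(.n_bonds(mol))) {
      if (!ringb[k]) { has_acyclic[mol$ba[k]] <- TRUE; has_acyclic[mol$bb[k]] <- TRUE }
    }
    branched <- branched & has_acyclic
  }
  c(ring_count = as.integer(.ring_count(mol)),
    branch_count = as.integer(sum(branched)))
}

#' Morgan (circular) fingerprint, radius 2
#'
#' Deterministic 2048-bit hashed circular fingerprint. Atom environments of
#' radius 0, 1 and 2 are hashed from the iterated Morgan invariants (element,
#' degree, hydrogen count, charge, aromaticity, ring membership) and folded
#' into \code{n_bits} bits.
#'
#' @param mol SMILES string, parsed molecule or \code{standard_mol}.
#' @param n_bits fingerprint length (default 2048).
#' @return Sorted integer vector of set-bit positions (1-based), with
#'   attribute \code{n_bits}; see \code{\link{tanimoto}}.
#' @export
ecfp4 <- function(mol, n_bits = 2048L) {
  mol <- .as_mol(mol)
  n <- .n_atoms(mol)
  adj <- .adjlist(mol)
  ringb <- .ring_bond_flags(mol)
  inring <- rep(FALSE, n)
  inring[mol$ba[ringb]] <- TRUE; inring[mol$bb[ringb]] <- TRUE
  deg <- .degree(mol)
  MODP <- 2147483629
  hash_str <- function(s) {
    v <- utf8ToInt(s)
    h <- 2166136261 %% MODP
    for (x in v) h <- (h * 31 + x) %% MODP
    h
  }
  inv <- vapply(seq_len(n), function(i)
    hash_str(sprintf("%s|%d|%d|%d|%d|%d", mol$elem[i], deg[i], mol$hcount[i],
                     mol$charge[i], as.integer(mol$arom[i]), as.integer(inring[i]))),
    numeric(1))
  codes <- inv
  cur <- inv
  for (r in 1:2) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb$atom) == 0) { nxt[i] <- (cur[i] * 31 + 7) %% MODP; next }
      parts <- vapply(seq_along(nb$atom), function(j) {
        k <- nb$bond[j]
        bc <- if (mol$barom[k]) 4 else mol$border[k]
        sprintf("%d:%.0f", bc, cur[nb$atom[j]])
      }, character(1))
      nxt[i] <- hash_str(sprintf("%.0f|%s", cur[i], paste(sort(parts), collapse = ",")))
    }
    cur <- nxt
    codes <- c(codes, cur)
  }
  bits <- sort(unique(as.integer(codes %% n_bits) + 1L))
  structure(bits, n_bits = as.integer(n_bits), codes = codes, class = "mf_fp")
}

#' Tanimoto similarity between two fingerprints
#'
#' \code{|A intersect B| / |A union B|} over the set bits of two fingerprints
#' from \code{\link{ecfp4}}.
#'
#' @param a,b fingerprints (set-bit integer vectors).
#' @return similarity in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Randomized SMILES rendering
#'
#' Writes the molecule from a random atom ordering, producing an alternative
#' valid SMILES of the same molecule (used for on-the-fly training
#' augmentation). Canonicalizing the output recovers the canonical SMILES.
#'
#' @param mol SMILES string, parsed molecule or \code{standard_mol}.
#' @param rng optional function \code{rng(n)} returning a permutation of
#'   \code{1..n}; defaults to \code{sample} under the current RNG state.
#' @return A SMILES string.
#' @export
randomize_smiles <- function(mol, rng = NULL) {
  mol <- .as_mol(mol)
  n <- .n_atoms(mol)
  perm <- if (is.null(rng)) sample.int(n) else rng(n)
  smi_write(mol, order(perm))
}

#' Canonical nonisomeric SMILES
#'
#' @param smiles SMILES string (or parsed molecule).
#' @return canonical SMILES string; errors on unparseable input.
#' @export
canonicalize <- function(smiles) smi_canonical(smiles)

#' Is a SMILES string chemically valid?
#'
#' Syntactic parse plus valence and aromaticity checks (every aromatic atom
#' must lie in an aromatic ring; isolated aromatic rings must satisfy the
#' Huckel 4n+2 electron count).
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s)
    !inherits(tryCatch(smi_parse(s), error = function(e) e), "error"),
    logical(1), USE.NAMES = FALSE)
}

#' Read a SMILES collection
#'
#' Reads either a \code{.smi} file (one SMILES per line, optional
#' whitespace-separated identifier) or a CSV with a SMILES column.
#'
#' @param path file path.
#' @param smiles_col CSV column holding SMILES (default \code{"smiles"}).
#' @return data.frame with columns \code{smiles} and \code{id}.
#' @export
read_smiles <- function(path, smiles_col = "smiles") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!smiles_col %in% names(df))
      stop("column '", smiles_col, "' not found in ", path)
    ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(nrow(df)))
    return(data.frame(smiles = as.character(df[[smiles_col]]), id = ids,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(smiles = vapply(parts, `[`, character(1), 1),
             id = vapply(seq_along(parts), function(i)
               if (length(parts[[i]]) > 1) parts[[i]][2] else as.character(i),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Curate a SMILES collection
#'
#' Standardizes every input SMILES, deduplicates on canonical SMILES and
#' reports per-row outcomes. Optionally profiles each kept molecule against a
#' functional-group ontology.
#'
#' @param smiles character vector of raw SMILES.
#' @param ontology optional \code{smartsrx_ontology} for descriptor profiling.
#' @return list with \code{molecules} (list of \code{standard_mol}),
#'   \code{table} (data.frame: smiles, scaffold, descriptor_ids, ring_count,
#'   branch_count, rejection_reason) and \code{counts}
#'   (input / kept / rejected / duplicate).
#' @export
curate_smiles <- function(smiles, ontology = NULL) {
  seen <- character(0)
  mols <- list()
  rows <- vector("list", length(smiles))
  n_rej <- 0L; n_dup <- 0L
  for (i in seq_along(smiles)) {
    sm <- standardize(smiles[i])
    if (inherits(sm, "mol_rejection")) {
      n_rej <- n_rej + 1L
      rows[[i]] <- data.frame(smiles = smiles[i], scaffold = NA, descriptor_ids = NA,
                              ring_count = NA, branch_count = NA,
                              rejection_reason = sm$reason, stringsAsFactors = FALSE)
      next
    }
    if (sm$canonical_smiles %in% seen) {
      n_dup <- n_dup + 1L
      rows[[i]] <- data.frame(smiles = smiles[i], scaffold = NA, descriptor_ids = NA,
                              ring_count = NA, branch_count = NA,
                              rejection_reason = "duplicate", stringsAsFactors = FALSE)
      next
    }
    seen <- c(seen, sm$canonical_smiles)
    ids <- if (is.null(ontology)) character(0) else profile(sm, ontology)
    sm$descriptor_ids <- ids
    mols[[length(mols) + 1L]] <- sm
    rows[[i]] <- data.frame(smiles = sm$canonical_smiles, scaffold = sm$scaffold_smiles,
                            descriptor_ids = paste(ids, collapse = ";"),
                            ring_count = sm$ring_count, branch_count = sm$branch_count,
                            rejection_reason = "", stringsAsFactors = FALSE)
  }
  list(molecules = mols,
       table = do.call(rbind, rows),
       counts = c(input = length(smiles), kept = length(mols),
                  rejected = n_rej, duplicate = n_dup))
}
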