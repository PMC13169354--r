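# Synthetic fixtures: a miniature hierarchical functional-group ontology and
# a fragment-grammar corpus generator (core + linker + substituent) with
# per-molecule ground-truth annotations, so the full pipeline runs with no
# external data.

# bundled pattern library: id, level1 class, level2 group, SMARTS
.TOY_PATTERNS <- data.frame(
  id = c("Amide_NSub", "Ester_Alk", "Acid_Carboxylic", "Ketone_Dialkyl",
         "Aldehyde_Any", "Sulfonamide_Prim", "Sulfone_Any", "Thioether_Dialkyl",
         "Nitro_Any", "Nitrile_Any", "Amine_Prim", "Amine_Tert", "Imine_CN",
         "Ether_Dialkyl", "Alcohol_Alkyl", "Phenol_OH", "X-Cl_Ar", "X-F_Ar",
         "X-Br_Ar", "X-Hal_Alk", "Enone_Michael", "Ring_Pyridine",
         "Azole_NH", "Ring_Thiophene", "Ring_Furan", "Ring_Benzene"),
  level1 = c("Carbonyl", "Carbonyl", "Carbonyl", "Carbonyl", "Carbonyl",
             "Sulfur", "Sulfur", "Sulfur", "Nitrogen", "Nitrogen", "Nitrogen",
             "Nitrogen", "Nitrogen", "Oxygen", "Oxygen", "Oxygen", "Halogen",
             "Halogen", "Halogen", "Halogen", "Alert", "Heteroaromatic",
             "Heteroaromatic", "Heteroaromatic", "Heteroaromatic", "Aromatic"),
  level2 = c("Amide", "Ester", "Acid", "Ketone", "Aldehyde", "Sulfonamide",
             "Sulfone", "Thioether", "Nitro", "Nitrile", "Amine", "Amine",
             "Imine", "Ether", "Alcohol", "Phenol", "ArylHalide", "ArylHalide",
             "ArylHalide", "AlkylHalide", "MichaelAcceptor", "Azine", "Azole",
             "Thiophene", "Furan", "Benzene"),
  smarts = c("[CX3](=O)[NX3]", "[CX3](=O)[OX2][#6]", "[CX3](=O)[OX2H]",
             "[#6][CX3](=O)[#6]", "[CX3H1]=O", "[SX4](=O)(=O)[NX3]",
             "[SX4](=O)(=O)([#6])[#6]", "[#6X4][SX2][#6]", "[NX3+](=O)[O-]",
             "[CX2]#[NX1]", "[NX3H2][#6]", "[NX3]([CX4])([CX4])[#6]",
             "[CX3]=[NX2]", "[#6][OX2][#6]", "[OX2H][CX4]", "[OX2H]c",
             "Clc", "Fc", "Brc", "[CX4][F,Cl,Br,I]",
             "[CX3]=[CX3][CX3]=[OX1]", "n1ccccc1", "[nH]", "c1ccsc1",
             "c1ccoc1", "c1ccccc1"),
  stringsAsFactors = FALSE
)

#' Miniature functional-group ontology
#'
#' Returns the first \code{k} entries of the bundled ~26-pattern library as a
#' validated three-level ontology, mirroring the structure of the full
#' hierarchical SMARTS ontology used for conditioning.
#'
#' @param k number of entries (default: all).
#' @return a \code{smartsrx_ontology}.
#' @export
make_toy_ontology <- function(k = nrow(.TOY_PATTERNS)) {
  if (k > nrow(.TOY_PATTERNS))
    stop("k too large: bundled library has ", nrow(.TOY_PATTERNS), " patterns")
  if (k == 0)
    return(structure(.TOY_PATTERNS[0, ], class = c("smartsrx_ontology", "data.frame")))
  as_ontology(.TOY_PATTERNS[seq_len(k), ])
}

# grammar tables -------------------------------------------------------------
# cores: template with %s slots for optional "(branch)" insertions
.TOY_CORES <- list(
  benzene     = list(tpl = "c1c%scc%scc1",      nslot = 2, aromatic = TRUE,
                     gt = "Ring_Benzene"),
  pyridine    = list(tpl = "c1cc%sccn1",        nslot = 1, aromatic = TRUE,
                     gt = "Ring_Pyridine"),
  thiophene   = list(tpl = "c1cc%scs1",         nslot = 1, aromatic = TRUE,
                     gt = "Ring_Thiophene"),
  cyclohexane = list(tpl = "C1CC%sCC%sC1",      nslot = 2, aromatic = FALSE,
                     gt = character(0)),
  piperidine  = list(tpl = "C1CC%sCCN1",        nslot = 1, aromatic = FALSE,
                     gt = character(0)),
  naphthalene = list(tpl = "c1ccc2cc%sccc2c1",  nslot = 1, aromatic = TRUE,
                     gt = "Ring_Benzene")
)

# substituents: branch SMILES, ground-truth descriptors when attached directly
# to an aromatic carbon (gt_ar) vs an sp3 carbon (gt_alk), whether a carbon
# linker may be inserted, and an alert flag (structurally alerting fragments)
.TOY_SUBS <- list(
  chloro    = list(smi = "Cl",           gt_ar = "X-Cl_Ar",  gt_alk = "X-Hal_Alk", linker = FALSE, alert = FALSE),
  fluoro    = list(smi = "F",            gt_ar = "X-F_Ar",   gt_alk = "X-Hal_Alk", linker = FALSE, alert = FALSE),
  bromo     = list(smi = "Br",           gt_ar = "X-Br_Ar",  gt_alk = "X-Hal_Alk", linker = FALSE, alert = FALSE),
  hydroxy   = list(smi = "O",            gt_ar = "Phenol_OH", gt_alk = "Alcohol_Alkyl", linker = FALSE, alert = FALSE),
  methoxy   = list(smi = "OC",           gt_ar = "Ether_Dialkyl", gt_alk = "Ether_Dialkyl", linker = FALSE, alert = FALSE),
  amino     = list(smi = "N",            gt_ar = "Amine_Prim", gt_alk = "Amine_Prim", linker = TRUE, alert = FALSE),
  ester     = list(smi = "C(=O)OC",      gt_ar = "Ester_Alk", gt_alk = "Ester_Alk", linker = TRUE, alert = FALSE),
  acid      = list(smi = "C(=O)O",       gt_ar = "Acid_Carboxylic", gt_alk = "Acid_Carboxylic", linker = TRUE, alert = FALSE),
  amide     = list(smi = "C(=O)NC",      gt_ar = "Amide_NSub", gt_alk = "Amide_NSub", linker = TRUE, alert = FALSE),
  acetyl    = list(smi = "C(=O)C",       gt_ar = "Ketone_Dialkyl", gt_alk = "Ketone_Dialkyl", linker = TRUE, alert = FALSE),
  nitrile   = list(smi = "C#N",          gt_ar = "Nitrile_Any", gt_alk = "Nitrile_Any", linker = TRUE, alert = FALSE),
  nitro     = list(smi = "[N+](=O)[O-]", gt_ar = "Nitro_Any", gt_alk = "Nitro_Any", linker = FALSE, alert = TRUE),
  sulfonamide = list(smi = "S(=O)(=O)N", gt_ar = "Sulfonamide_Prim", gt_alk = "Sulfonamide_Prim", linker = FALSE, alert = FALSE),
  thiomethyl  = list(smi = "SC",         gt_ar = "Thioether_Dialkyl", gt_alk = "Thioether_Dialkyl", linker = FALSE, alert = FALSE),
  enone     = list(smi = "C=CC(C)=O",    gt_ar = c("Enone_Michael", "Ketone_Dialkyl"),
                   gt_alk = c("Enone_Michael", "Ketone_Dialkyl"), linker = TRUE, alert = TRUE),
  dimethylamino = list(smi = "N(C)C",    gt_ar = "Amine_Tert", gt_alk = "Amine_Tert", linker = TRUE, alert = FALSE)
)
.TOY_LINKERS <- c("", "C", "CC")

#' Specification for the synthetic toy corpus
#'
#' The generator emulates a small drug-like corpus assembled from a fragment
#' grammar: a ring core, optionally substituted at one or two positions, each
#' substituent attached directly or through a short alkyl linker. Alerting
#' fragments (nitro, Michael-acceptor enone) are down-weighted so that alert
#' content is a controllable minority, mirroring a curated drug-like corpus.
#'
#' @param n_molecules number of unique molecules to emit.
#' @param seed RNG seed.
#' @param alert_weight sampling weight of alert-bearing substituents relative
#'   to 1 for ordinary substituents (default 0.35).
#' @param p_second_sub probability of a second substituent where the core
#'   allows one (default 0.6).
#' @param n_overlength number of deliberately over-long molecules (long alkyl
#'   tails) appended to exercise the sequence-length filter (default 0).
#' @param cores subset of core names to use (default: all six).
#' @param unique_profiles logical; when TRUE, additionally deduplicate on the
#'   (core, ground-truth descriptor set) key so that every molecule has a
#'   distinct conditioning context. Needed when the corpus feeds
#'   prompt-conditioned reconstruction experiments, where an injective
#'   context-to-target map is a precondition of the measurement.
#' @return object of class \code{toy_corpus_spec}.
#' @export
toy_corpus_spec <- function(n_molecules = 100, seed = 1, alert_weight = 0.35,
                            p_second_sub = 0.6, n_overlength = 0,
                            cores = names(.TOY_CORES), unique_profiles = FALSE) {
  stopifnot(n_molecules >= 1, all(cores %in% names(.TOY_CORES)))
  structure(list(n_molecules = n_molecules, seed = seed,
                 alert_weight = alert_weight, p_second_sub = p_second_sub,
                 n_overlength = n_overlength, cores = cores,
                 unique_profiles = unique_profiles),
            class = "toy_corpus_spec")
}

#' Generate the synthetic toy corpus
#'
#' Emits \code{n_molecules} unique, valid, standardizable SMILES with
#' ground-truth annotations: which core (hence which Bemis-Murcko scaffold)
#' and which substituents (hence which toy-ontology descriptors) each
#' molecule contains by construction. The profile of a molecule against the
#' toy ontology is always a superset of its ground-truth descriptors.
#'
#' @param spec a \code{toy_corpus_spec} (or an integer, shorthand for
#'   \code{toy_corpus_spec(n_molecules = spec)}).
#' @return list with \code{smiles} (character), \code{truth} (data.frame:
#'   smiles, core, scaffold, gt_descriptors (semicolon-joined), has_alert)
#'   and \code{spec}.
#' @export
make_toy_corpus <- function(spec) {
  if (is.numeric(spec)) spec <- toy_corpus_spec(n_molecules = spec)
  stopifnot(inherits(spec, "toy_corpus_spec"))
  set.seed(spec$seed)
  subs <- .TOY_SUBS
  w <- vapply(subs, function(s) if (s$alert) spec$alert_weight else 1, numeric(1))
  seen <- character(0)
  seen_profiles <- character(0)
  onto <- if (isTRUE(spec$unique_profiles)) make_toy_ontology() else NULL
  out <- list()
  std_cache <- new.env(hash = TRUE)   # raw assembly -> standard_mol (repeats are common)
  consecutive_fail <- 0L
  max_fail <- max(500L, 10L * spec$n_molecules)
  while (length(out) < spec$n_molecules) {
    if (consecutive_fail > max_fail)
      stop("exhausted: grammar cannot reach n unique molecules")
    cname <- sample(spec$cores, 1)
    core <- .TOY_CORES[[cname]]
    nsub <- if (core$nslot >= 2 && stats::runif(1) < spec$p_second_sub) 2L else 1L
    pick <- sample(names(subs), nsub, replace = FALSE, prob = w[names(subs)])
    branches <- character(core$nslot)
    gt <- core$gt
    alert <- FALSE
    for (j in seq_len(nsub)) {
      su <- subs[[pick[j]]]
      use_linker <- su$linker && stats::runif(1) < 0.4
      lk <- if (use_linker) sample(.TOY_LINKERS[-1], 1) else ""
      branches[j] <- sprintf("(%s%s%s)", lk, su$smi, "")
      attach_arom <- core$aromatic && lk == ""
      gt <- union(gt, if (attach_arom) su$gt_ar else su$gt_alk)
      alert <- alert || su$alert
    }
    smi <- do.call(sprintf, c(list(core$tpl), as.list(branches)))
    sm <- std_cache[[smi]]
    if (is.null(sm)) {
      sm <- standardize(smi, fingerprint = FALSE)
      std_cache[[smi]] <- sm
    }
    if (inherits(sm, "mol_rejection")) { consecutive_fail <- consecutive_fail + 1L; next }
    can <- sm$canonical_smiles
    if (can %in% seen) { consecutive_fail <- consecutive_fail + 1L; next }
    if (isTRUE(spec$unique_profiles)) {
      # key on the *realized* profile (a superset of the ground truth) so the
      # (descriptors, scaffold) -> molecule map is injective
      pkey <- paste(sm$scaffold_smiles,
                    paste(sort(profile(sm, onto)), collapse = ";"), sep = "|")
      if (pkey %in% seen_profiles) { consecutive_fail <- consecutive_fail + 1L; next }
      seen_profiles <- c(seen_profiles, pkey)
    }
    consecutive_fail <- 0L
    seen <- c(seen, can)
    out[[length(out) + 1L]] <- data.frame(
      smiles = can, core = cname, scaffold = sm$scaffold_smiles,
      gt_descriptors = paste(sort(gt), collapse = ";"),
      has_alert = alert, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out)
  if (spec$n_overlength > 0) {
    long <- vapply(seq_len(spec$n_overlength), function(i)
      paste0("c1ccc(cc1)", strrep("C", 140 + i)), character(1))
    truth <- rbind(truth, data.frame(
      smiles = vapply(long, function(s) standardize(s, fingerprint = FALSE)$canonical_smiles,
                      character(1), USE.NAMES = FALSE),
      core = "benzene", scaffold = "c1ccccc1",
      gt_descriptors = "Ring_Benzene", has_alert = FALSE,
      stringsAsFactors = FALSE))
  }
  list(smiles = truth$smiles, truth = truth, spec = spec)
}

#' Scaffold SMILES of each bundled toy core
#' @return named character vector (core name -> canonical scaffold SMILES).
#' @export
toy_core_scaffolds <- function() {
  vapply(.TOY_CORES, function(co) smi_canonical(smi_parse(gsub("%s", "", co$tpl))),
         character(1))
}
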