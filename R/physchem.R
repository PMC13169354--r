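# Physicochemical profiling: MW, logP, H-bond donors/acceptors, rotatable
# bonds, ring counts, TPSA, Lipinski Ro5, structural alerts, PAINS flags,
# QED (Bickerton et al. desirability functions) and a corpus-referenced
# synthetic-accessibility heuristic. logP and TPSA come from OpenBabel;
# graph-derived counts come from the internal engine.

.ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.086,
                  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
                  Ca = 40.078, As = 74.922, Se = 78.96, Br = 79.904,
                  I = 126.904)

#' Molecular weight (average atomic masses, implicit H included)
#' @param mol SMILES string or parsed molecule.
#' @return weight in Da.
#' @export
mol_weight <- function(mol) {
  mol <- .as_mol(mol)
  m <- .ATOMIC_MASS[mol$elem]
  m[is.na(m)] <- 0
  sum(m) + sum(mol$hcount) * .ATOMIC_MASS[["H"]]
}

# Lipinski-style counts on the internal graph
.hbd_count <- function(mol) sum(mol$elem %in% c("N", "O") & mol$hcount > 0)
.hba_count <- function(mol) sum(mol$elem %in% c("N", "O"))

.rotatable_bonds <- function(mol) {
  ringb <- .ring_bond_flags(mol)
  deg <- .degree(mol)
  n_rot <- 0L
  for (k in seq_len(.n_bonds(mol))) {
    if (ringb[k] || mol$border[k] != 1 || mol$barom[k]) next
    a <- mol$ba[k]; b <- mol$bb[k]
    if (deg[a] < 2 || deg[b] < 2) next
    # exclude amide C-N
    amide <- FALSE
    for (end in list(c(a, b), c(b, a))) {
      if (mol$elem[end[1]] == "C" && mol$elem[end[2]] == "N") {
        nb <- .adjlist(mol)[[end[1]]]
        for (j in seq_along(nb$atom)) {
          if (mol$elem[nb$atom[j]] == "O" && mol$border[nb$bond[j]] == 2) amide <- TRUE
        }
      }
    }
    if (!amide) n_rot <- n_rot + 1L
  }
  n_rot
}

.aromatic_ring_count <- function(mol) {
  rings <- .sssr(mol)
  sum(vapply(rings, function(r) all(mol$arom[r]), logical(1)))
}

# OpenBabel-computed descriptors (logP, TPSA) for a canonical SMILES
.ob_props <- function(smiles) {
  p <- ChemmineOB::prop_OB(.obmol(smiles))
  list(logp = as.numeric(p$logP), tpsa = as.numeric(p$TPSA))
}

# QED desirability parameters (Bickerton et al., Nat. Chem. 2012): asymmetric
# double sigmoid coefficients (a, b, c, d, e, f, dmax) per property, and the
# mean-weights scheme.
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                  ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  exp1 <- 1 + exp(-(x - cc + d / 2) / e)
  exp2 <- 1 + exp(-(x - cc - d / 2) / f)
  (a + b / exp1 * (1 - 1 / exp2)) / dmax
}

# hydrogen-bond acceptor definition used inside QED (SMARTS census)
.QED_ACCEPTOR_SMARTS <- c(
  "[oH0;X2]", "[OH1;X2;v2]", "[OH0;X2;v2]", "[OH0;X1;v2]", "[O-;X1]",
  "[SH0;X2;v2]", "[SH0;X1;v2]", "[S-;X1]", "[nH0;X2]", "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]")

# structural-alert list used inside the QED ALERTS component (Brenk-style
# unwanted functionalities, as published with the QED definition). Patterns
# the SMARTS backend cannot compile are skipped once with a note.
.QED_ALERT_SMARTS <- c(
  "*1[O,S,N]*1", "[S,C](=[O,S])[F,Br,Cl,I]", "[CX4][Cl,Br,I]", "[#6]S(=O)(=O)O[#6]",
  "[$([CH]),$(CC)]#CC(=O)[#6]", "[$([CH]),$(CC)]#CC(=O)O[#6]", "n[OH]",
  "[$([CH]),$(CC)]#CS(=O)(=O)[#6]", "C=C(C=O)C=O", "n1c([F,Cl,Br,I])cccc1", "[CH1](=O)",
  "[#8][#8]", "[C;!R]=[N;!R]", "[N!R]=[N!R]", "[#6](=O)[#6](=O)", "[#16][#16]",
  "[#7][NH2]", "C(=O)N[NH2]", "[#6]=S",
  "[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]",
  "C1(=[O,N])C=CC(=[O,N])C=C1", "C1(=[O,N])C(=[O,N])C=CC=C1", "a21aa3a(aa1aaaa2)aaaa3",
  "a31a(a2a(aa1)aaaa2)aaaa3", "c1cc([NH2])ccc1",
  "[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si,Na,Ca,Ge,Ag,Mg,K,Ba,Sr,Be,Ti,Mo,Mn,Ru,Pd,Ni,Cu,Au,Cd,Al,Ga,Sn,Rh,Tl,Bi,Nb,Li,Pb,Hf,Ho]",
  "I", "OS(=O)(=O)[O-]", "[N+](=O)[O-]", "C(=O)N[OH]", "C1NC(=O)NC(=O)1", "[SH]", "[S-]",
  "c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "[CR1]1[CR1][CR1][CR1][CR1][CR1][CR1]1", "[CR1]1[CR1][CR1]cc[CR1][CR1]1",
  "[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1", "[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1", "C#C",
  "[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]",
  "[$([N+R]),$([n+R]),$([N+]=C)][O-]", "[#6]=N[OH]", "[#6]=NOC=O",
  "[#6](=O)[CX4,CR0X3,O][#6](=O)", "c1ccc2c(c1)ccc(=O)o2", "[O+,o+,S+,s+]", "N=C=O",
  "[NX3,NX4][F,Cl,Br,I]", "c1ccccc1OC(=O)[#6]", "[CR0]=[CR0][CR0]=[CR0]",
  "[C+,c+,C-,c-]", "N=[N+]=[N-]", "C12C(NC(N1)=O)CSC2", "c1c([OH])c([OH,NH2,NH])ccc1", "P",
  "[N,O,S]C#N", "C=C=O", "[Si][F,Cl,Br,I]", "[SX2]O",
  "[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)", "O1CCCCC1OC2CCC3CCCCC3C2", "N=[CR0][N,n,O,S]",
  "[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2",
  "C=[C!r]C#N", "[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])", "[OH]c1ccc([OH,NH2,NH])cc1",
  "c1ccccc1OC(=O)O", "[SX2H0][N]", "c12ccccc1(SC(S)=N2)", "c12ccccc1(SC(=S)N2)",
  "c1nnnn1C=O", "s1c(S)nnc1NC=O", "S1C=CSC1=S", "C(=O)Onnn", "OS(=O)(=O)C(F)(F)F",
  "N#CC[OH]", "N#CC(=O)", "S(=O)(=O)C#N", "N[CH2]C#N", "C1(=O)NCC1", "S(=O)(=O)[O-,OH]",
  "NC[F,Cl,Br,I]", "C=[C!r]O", "[NX2+0]=[O+0]", "[OR0,NR0][OR0,NR0]", "[CX2R0][NX3R0]",
  "c1ccccc1[C;!R]=[C;!R]c2ccccc2",
  "[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]",
  "[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]",
  "[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]", "[*]=[N+]=[*]",
  "[SX3](=O)[O-,OH]", "N#N", "[R0;D2][R0;D2][R0;D2][R0;D2]",
  "[cR,CR]~C(=O)NC(=O)~[cR,CR]", "C=!@CC=[O,S]", "[#6,#8,#16][#6](=O)O[#6]",
  "c[C;R0](=[O,S])[#6]", "c[SX2][C;!R]", "C=C=C", "c1nc([F,Cl,Br,I,S])ncc1",
  "c1ncnc([F,Cl,Br,I,S])c1", "c1nc(c2c(n1)nc(n2)[F,Cl,Br,I])",
  "[#6]S(=O)(=O)c1ccc(cc1)F")

# representative subset of published PAINS filters (the full catalog has ~480
# patterns; this subset flags the most common promiscuity chemotypes)
.PAINS_SMARTS <- c(
  quinone_A      = "O=C1C(=O)C=CC=C1",
  quinone_B      = "O=C1C=CC(=O)C=C1",
  catechol       = "[OH]c1ccc(cc1)[OH]",
  catechol_ortho = "[OH]c1cccc(c1)[OH]",
  hydroxyphenyl_hydrazone = "[OH]c1ccccc1C=N",
  rhodanine      = "S=C1NC(=O)CS1",
  ene_rhodanine  = "S=C1NC(=O)C(=C)S1",
  alkylidene_barbiturate = "O=C1NC(=O)NC(=O)C1=C",
  imine_phenol   = "C=Nc1ccccc1[OH]",
  enamine_nitrile = "N=C(C#N)",
  azo_aryl       = "cN=Nc",
  isothiazolone  = "S1C=CC(=O)N1",
  curcumin_enone = "C(=O)C=Cc1ccccc1[OH]",
  beta_keto_anilide = "O=C(C=O)Nc1ccccc1",
  mannich_phenol = "[OH]c1ccccc1CN")

.compiled_smarts_hits <- function(smiles, patterns) {
  ob <- .obmol(smiles)
  vapply(patterns, function(p)
    tryCatch(ChemmineOB::smartsSearch_OB(ob, p) > 0,
             error = function(e) NA),
    logical(1))
}

#' Structural-alert and PAINS counts
#'
#' \code{alerts} counts matches against the unwanted-functionality list used
#' inside the QED ALERTS component; \code{pains} against a representative
#' subset of the PAINS filters. Patterns the backend cannot compile are
#' excluded from the census.
#'
#' @param smiles character scalar (canonical SMILES recommended).
#' @return list(alerts =, pains =).
#' @export
alert_counts <- function(smiles) {
  a <- .compiled_smarts_hits(smiles, .QED_ALERT_SMARTS)
  p <- .compiled_smarts_hits(smiles, .PAINS_SMARTS)
  list(alerts = sum(a, na.rm = TRUE), pains = sum(p, na.rm = TRUE))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of eight desirability functions (MW, logP, HBA,
#' HBD, PSA, rotatable bonds, aromatic rings, structural alerts) with the
#' published mean-weights scheme. logP and TPSA are OpenBabel values, so
#' absolute QED scores differ slightly from implementations built on other
#' property calculators; the component breakdown (including the ALERTS
#' count) is exposed for decomposition analyses.
#'
#' @param smiles character scalar.
#' @return list(qed =, components = named numeric of the raw property
#'   values, desirabilities = named numeric).
#' @export
qed_score <- function(smiles) {
  mol <- smi_parse(smiles)
  ob <- .ob_props(smiles)
  obm <- .obmol(smiles)
  nacc <- sum(vapply(.QED_ACCEPTOR_SMARTS, function(p)
    tryCatch(ChemmineOB::smartsSearch_OB(obm, p), error = function(e) 0),
    numeric(1)))
  comp <- c(MW = mol_weight(mol), ALOGP = ob$logp, HBA = nacc,
            HBD = .hbd_count(mol), PSA = ob$tpsa,
            ROTB = .rotatable_bonds(mol), AROM = .aromatic_ring_count(mol),
            ALERTS = alert_counts(smiles)$alerts)
  des <- vapply(names(comp), function(nm) .ads(comp[[nm]], .QED_ADS[[nm]]),
                numeric(1))
  w <- .QED_WEIGHTS[names(comp)]
  list(qed = exp(sum(w * log(pmax(des, 1e-12))) / sum(w)),
       components = comp, desirabilities = des)
}

#' Physicochemical profile of a molecule set
#'
#' Per-molecule values of the compared properties (MW, logP, ring count,
#' HBD, HBA, rotatable bonds, aromatic rings, TPSA, QED, SA score, alerts,
#' PAINS flag, Ro5) plus a mean +/- sd summary.
#'
#' @param smiles character vector of valid SMILES.
#' @param sa_reference optional fragment-score table from
#'   \code{\link{sa_fragment_scores}}; SA is NA when absent.
#' @return list(table = per-molecule data.frame, summary = data.frame with
#'   mean and sd per property).
#' @export
physchem_profile <- function(smiles, sa_reference = NULL) {
  rows <- lapply(smiles, function(s) {
    mol <- smi_parse(s)
    q <- qed_score(s)
    al <- alert_counts(s)
    hbd <- .hbd_count(mol); hba <- .hba_count(mol)
    mw <- mol_weight(mol); lp <- q$components[["ALOGP"]]
    viol <- sum(mw > 500, lp > 5, hbd > 5, hba > 10)
    data.frame(smiles = s, mw = mw, logp = lp,
               ring_count = as.integer(.ring_count(mol)),
               hbd = hbd, hba = hba,
               rotatable_bonds = .rotatable_bonds(mol),
               aromatic_rings = .aromatic_ring_count(mol),
               tpsa = q$components[["PSA"]],
               qed = q$qed, alerts = al$alerts, pains = al$pains,
               sa_score = if (is.null(sa_reference)) NA_real_
                          else sa_score(s, sa_reference),
               ro5_violations = viol, ro5_pass = viol <= 1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, !(names(tab) %in% c("smiles", "ro5_pass")), drop = FALSE]
  summ <- data.frame(property = names(num),
                     mean = vapply(num, function(x) mean(as.numeric(x)), numeric(1)),
                     sd = vapply(num, function(x) stats::sd(as.numeric(x)), numeric(1)))
  list(table = tab, summary = summ)
}

# --- synthetic accessibility ----------------------------------------------

#' Fragment score table for the synthetic-accessibility heuristic
#'
#' The SA heuristic scores circular-fragment familiarity against a reference
#' corpus: fragment contributions are centered log-frequencies of Morgan
#' environment codes across the reference set (frequent fragments score
#' high, rare fragments low), standing in for a fixed precomputed fragment
#' library.
#'
#' @param reference_smiles character vector of reference molecules.
#' @return environment mapping fragment code -> score (class
#'   \code{mf_sa_reference}).
#' @export
sa_fragment_scores <- function(reference_smiles) {
  counts <- new.env(hash = TRUE)
  for (s in reference_smiles) {
    codes <- .morgan_codes(smi_parse(s))
    for (cd in unique(codes)) {
      key <- as.character(cd)
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  vals <- vapply(keys, function(k) counts[[k]], numeric(1))
  lf <- log(vals / sum(vals))
  lf <- lf - max(lf)                       # most common fragment scores 0
  scores <- new.env(hash = TRUE)
  for (i in seq_along(keys)) scores[[keys[i]]] <- lf[i]
  class(scores) <- c("mf_sa_reference", "environment")
  scores
}

# all Morgan environment codes (radius 0..2) of a molecule
.morgan_codes <- function(mol) {
  fp <- ecfp4(mol)
  attr(fp, "codes")
}

#' Synthetic-accessibility score (corpus-referenced heuristic)
#'
#' Ertl-style structure: a fragment-familiarity term (mean fragment score
#' against the reference table; unseen fragments get the floor score) minus
#' complexity penalties (size, ring fusion, macrocycles), mapped to the
#' conventional 1 (easy) to 10 (hard) scale.
#'
#' @param smiles character scalar.
#' @param reference an \code{mf_sa_reference}.
#' @return numeric score in [1, 10].
#' @export
sa_score <- function(smiles, reference) {
  mol <- smi_parse(smiles)
  codes <- unique(.morgan_codes(mol))
  floor_score <- -6
  fs <- vapply(as.character(codes), function(k) {
    v <- reference[[k]]
    if (is.null(v)) floor_score else v
  }, numeric(1))
  frag <- mean(fs)
  n <- .n_atoms(mol)
  size_penalty <- n^1.005 - n
  rings <- .sssr(mol)
  fused <- if (length(rings) < 2) 0 else {
    cnt <- table(unlist(rings)); sum(cnt > 1) / 2
  }
  macro <- sum(vapply(rings, length, integer(1)) > 8)
  raw <- frag - 0.5 * log(n) - log(fused + 1) - log(macro + 1) - size_penalty * 0.05
  # map raw (approx [-7, 0]) onto 1..10
  sc <- 1 + 9 * (-raw) / 7
  min(10, max(1, sc))
}
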