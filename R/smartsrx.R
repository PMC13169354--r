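# Hierarchical SMARTS functional-group ontology: loading, validation and
# per-molecule / per-corpus profiling. Substructure matching is delegated to
# OpenBabel (ChemmineOB); the ontology file is a TSV with a header row
# (id, level1, level2, smarts). Level-3 ids are the descriptor tokens used
# for conditioning.

#' Load a hierarchical SMARTS ontology
#'
#' Reads a tab-separated ontology file with columns \code{id} (Level-3 name,
#' the conditioning token), \code{level1} (class), \code{level2} (group) and
#' \code{smarts}. Every id must be unique and every SMARTS pattern must
#' compile; loading fails loudly otherwise (silent vocabulary drift would
#' corrupt the token space).
#'
#' @param path TSV file path.
#' @return \code{smartsrx_ontology}: data.frame (id, level1, level2, smarts).
#' @export
load_ontology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "level1", "level2", "smarts")
  if (!all(need %in% names(df)))
    stop("ontology file must have columns: ", paste(need, collapse = ", "))
  as_ontology(df[, need])
}

#' Construct an ontology from a data.frame
#'
#' @param df data.frame with columns id, level1, level2, smarts.
#' @return validated \code{smartsrx_ontology}.
#' @export
as_ontology <- function(df) {
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0)
    stop("duplicate_id: ", paste(unique(dup), collapse = ", "))
  probe <- .obmol("C")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ ChemmineOB::smartsSearch_OB(probe, df$smarts[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS at row ", i, " (id ", df$id[i], "): ", df$smarts[i])
  }
  structure(df, class = c("smartsrx_ontology", "data.frame"))
}

#' Write an ontology back to TSV
#' @param ontology a \code{smartsrx_ontology}.
#' @param path output path.
#' @export
write_ontology <- function(ontology, path) {
  utils::write.table(as.data.frame(ontology), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.smartsrx_ontology <- function(x, ...) {
  cat("<smartsrx_ontology>", nrow(x), "descriptors,",
      length(unique(x$level1)), "Level-1 classes\n")
  invisible(x)
}

.obmol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Functional-group profile of a molecule
#'
#' The set of ontology descriptors (presence flags, not match counts) whose
#' SMARTS pattern has at least one substructure match in the molecule.
#' Level 3 (default) returns descriptor ids; levels 2 and 1 project matches
#' through the hierarchy onto groups/classes.
#'
#' @param mol SMILES string, parsed molecule or \code{standard_mol}.
#' @param ontology a \code{smartsrx_ontology}.
#' @param level 1, 2 or 3 (default 3).
#' @return character vector of matched ids (ontology order).
#' @export
profile <- function(mol, ontology, level = 3) {
  if (nrow(ontology) == 0) return(character(0))
  smiles <- if (is.character(mol)) mol
            else if (inherits(mol, "standard_mol")) mol$canonical_smiles
            else smi_write(mol)
  ob <- .obmol(smiles)
  hit <- vapply(ontology$smarts, function(p)
    ChemmineOB::smartsSearch_OB(ob, p) > 0, logical(1), USE.NAMES = FALSE)
  ids <- ontology$id[hit]
  if (level == 3) return(ids)
  col <- if (level == 2) "level2" else "level1"
  out <- unique(ontology[[col]][hit])
  out[order(match(out, unique(ontology[[col]])))]
}

#' Per-class corpus frequency
#'
#' Percentage of corpus molecules containing at least one descriptor of each
#' Level-1 class (each molecule counted once per class).
#'
#' @param corpus list of \code{standard_mol} (or character SMILES vector).
#' @param ontology a \code{smartsrx_ontology}.
#' @return data.frame (class, percent), one row per Level-1 class in
#'   ontology order; percentages in \code{[0, 100]}.
#' @export
class_frequency <- function(corpus, ontology) {
  if (length(corpus) == 0) stop("empty_corpus")
  classes <- unique(ontology$level1)
  counts <- stats::setNames(numeric(length(classes)), classes)
  for (m in corpus) {
    cl <- profile(m, ontology, level = 1)
    counts[cl] <- counts[cl] + 1
  }
  data.frame(class = classes,
             percent = as.numeric(100 * counts / length(corpus)),
             stringsAsFactors = FALSE)
}

#' Descriptor-count statistics over a corpus
#'
#' Summary of the number of distinct Level-3 descriptors per molecule
#' (the semantic-fingerprint size).
#'
#' @param corpus list of \code{standard_mol} or character SMILES vector.
#' @param ontology a \code{smartsrx_ontology}.
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return named numeric \code{c(mean=, sd=, max=)}.
#' @export
descriptor_stats <- function(corpus, ontology, sd_type = c("sample", "population")) {
  if (length(corpus) == 0) stop("empty_corpus")
  sd_type <- match.arg(sd_type)
  counts <- vapply(corpus, function(m) length(profile(m, ontology)), numeric(1))
  n <- length(counts)
  s <- if (n < 2) 0 else {
    v <- stats::var(counts)
    if (sd_type == "population") sqrt(v * (n - 1) / n) else sqrt(v)
  }
  c(mean = mean(counts), sd = s, max = if (all(counts == 0)) 0 else max(counts))
}
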