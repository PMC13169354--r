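# Regex SMILES tokenizer and vocabulary over SMILES tokens, descriptor
# tokens and specials. Ids are 0-based with PAD fixed at 0.

SPECIAL_TOKENS <- c(PAD = "<PAD>", START = "[START]", SEP = "[SEP]", END = "[END]")

.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]+\\]",   # bracket atom (single token)
  "|%[0-9]{2}",      # multidigit ring closure
  "|Cl|Br",          # two-letter organic-subset atoms
  "|."               # any other single character
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' \code{[...]}, two-letter atoms \code{Cl}/\code{Br} and multidigit ring
#' closures \code{\%NN} are single tokens; everything else is one character
#' per token. Tokenization is purely syntactic (chemical validity is judged
#' elsewhere) and lossless: concatenating the tokens reproduces the input
#' byte-exactly.
#'
#' @param s character scalar.
#' @return character vector of tokens (length 0 for the empty string).
#' @examples
#' tokenize_smiles("ClCBr")     # "Cl" "C" "Br"
#' tokenize_smiles("C%12CC%12") # "C" "%12" "C" "C" "%12"
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (!nzchar(s)) return(character(0))
  m <- gregexpr(.SMILES_TOKEN_RE, s, perl = TRUE)[[1]]
  regmatches(s, list(m))[[1]]
}

#' Build a vocabulary over SMILES tokens, descriptor tokens and specials
#'
#' Id assignment is deterministic and order-independent with respect to
#' corpus shuffling: specials first (\code{<PAD>}=0, \code{[START]}=1,
#' \code{[SEP]}=2, \code{[END]}=3), then one token per ontology descriptor in
#' ontology order, then the corpus SMILES tokens in sorted order.
#'
#' @param token_lists list of character vectors (tokenized corpus SMILES).
#' @param ontology a \code{smartsrx_ontology} (its \code{id} column becomes
#'   the descriptor tokens); may have zero rows.
#' @return object of class \code{mf_vocab}: list with \code{tokens}
#'   (id-ordered), \code{ids} (named integer map), \code{specials},
#'   \code{descriptor_tokens}, \code{smiles_tokens}, \code{hash}.
#' @export
build_vocabulary <- function(token_lists, ontology) {
  if (length(token_lists) == 0) stop("empty corpus")
  smi_tok <- sort(unique(unlist(token_lists)))
  desc_tok <- as.character(ontology$id)
  clash <- intersect(smi_tok, c(unname(SPECIAL_TOKENS), desc_tok))
  if (length(clash) > 0)
    stop("corpus tokens collide with special/descriptor tokens: ",
         paste(clash, collapse = ", "))
  tokens <- c(unname(SPECIAL_TOKENS), desc_tok, smi_tok)
  ids <- stats::setNames(seq_along(tokens) - 1L, tokens)
  v <- list(tokens = tokens, ids = ids, specials = SPECIAL_TOKENS,
            descriptor_tokens = desc_tok, smiles_tokens = smi_tok)
  v$hash <- .vocab_hash(tokens)
  class(v) <- "mf_vocab"
  v
}

.vocab_hash <- function(tokens) {
  MODP <- 2147483629
  h <- 17
  for (x in utf8ToInt(paste(tokens, collapse = "\x1f"))) h <- (h * 31 + x) %% MODP
  sprintf("%010.0f", h)
}

#' @export
print.mf_vocab <- function(x, ...) {
  cat("<vocabulary>", length(x$tokens), "tokens (",
      length(x$descriptor_tokens), "descriptor,",
      length(x$smiles_tokens), "SMILES ) hash", x$hash, "\n")
  invisible(x)
}

#' Vocabulary size
#' @param vocab an \code{mf_vocab}.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Special-token id
#' @param vocab an \code{mf_vocab}.
#' @param which one of \code{"PAD"}, \code{"START"}, \code{"SEP"}, \code{"END"}.
#' @export
special_id <- function(vocab, which) {
  unname(vocab$ids[[SPECIAL_TOKENS[[which]]]])
}

#' Encode tokens to ids / decode ids to tokens
#'
#' Mutual inverses on their domains; unknown tokens and out-of-range ids are
#' hard errors (there is no UNK token).
#'
#' @param tokens character vector.
#' @param vocab an \code{mf_vocab}.
#' @return integer vector of 0-based ids.
#' @export
encode <- function(tokens, vocab) {
  if (length(tokens) == 0) return(integer(0))
  ids <- vocab$ids[tokens]
  if (anyNA(ids)) stop("oov_token: ", paste(unique(tokens[is.na(ids)]), collapse = ", "))
  unname(ids)
}

#' @rdname encode
#' @param ids integer vector of 0-based ids.
#' @export
decode <- function(ids, vocab) {
  if (length(ids) == 0) return(character(0))
  if (any(ids < 0 | ids >= length(vocab$tokens)))
    stop("id_out_of_range: ", paste(ids[ids < 0 | ids >= length(vocab$tokens)], collapse = ", "))
  vocab$tokens[ids + 1L]
}

#' Serialize / load a vocabulary as JSON
#'
#' The JSON holds the token-to-id map plus the descriptor-token list, so a
#' checkpoint can be reloaded with an identical token space.
#'
#' @param vocab an \code{mf_vocab}.
#' @param path JSON file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens,
                            descriptor_tokens = vocab$descriptor_tokens,
                            smiles_tokens = vocab$smiles_tokens,
                            hash = vocab$hash),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tokens <- as.character(j$tokens)
  v <- list(tokens = tokens,
            ids = stats::setNames(seq_along(tokens) - 1L, tokens),
            specials = SPECIAL_TOKENS,
            descriptor_tokens = as.character(j$descriptor_tokens),
            smiles_tokens = as.character(j$smiles_tokens),
            hash = .vocab_hash(tokens))
  if (!identical(v$hash, as.character(j$hash)))
    stop("vocabulary hash mismatch in ", path)
  class(v) <- "mf_vocab"
  v
}
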