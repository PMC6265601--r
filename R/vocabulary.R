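# Canonical descriptor/factor vocabularies. Token names are configuration
# (shipped as a fixture CSV); the cardinalities are part of the data model:
# 24 locations + 20 symptoms + 13 characteristics + 7 environments = 64
# descriptor flags and 15 aggravating + 14 alleviating + 14 ineffective = 43
# factor flags.

VOCAB_SIZES <- c(
  locations = 24L, symptoms = 20L, characteristics = 13L, environments = 7L,
  aggravating = 15L, alleviating = 14L, ineffective = 14L
)

DESCRIPTOR_VOCABS <- c("locations", "symptoms", "characteristics", "environments")
FACTOR_VOCABS <- c("aggravating", "alleviating", "ineffective")

#' @keywords internal
record_set_fields <- function() {
  c(locations = "locations", symptoms = "symptoms",
    characteristics = "characteristics", environments = "environments",
    aggravating = "aggravating_factors", alleviating = "alleviating_factors",
    ineffective = "ineffective_factors")
}

MEDICATION_CATEGORIES <- c("opioids", "tricyclics", "anticonvulsants",
                           "cannabinoids", "snris")

CONDITION_CATEGORIES <- c("fibromyalgia", "headaches", "back pain",
                          "arthritis", "depression-anxiety")

# Tokens the clinical composite flags refer to; must exist in the vocabulary.
NEUROPATHIC_CHARACTERISTICS <- c("pins and needles or tingling", "burning",
                                 "numbness", "electric shocks")
NEUROPATHIC_AGGRAVATING <- "light touch or clothing"
MENTAL_HEALTH_SYMPTOMS <- c("anxiety", "depression")
MENTAL_HEALTH_AGGRAVATING <- c("negative mood", "stress")

#' Load the canonical descriptor and factor vocabularies
#'
#' Reads a two-column CSV (`vocabulary`, `token`) and returns a named list of
#' ordered token vectors. Member order in the file is canonical: it fixes the
#' feature-column order of the descriptor and factor flag blocks. The default
#' fixture shipped with the package has the required cardinalities
#' (24/20/13/7 descriptors; 15/14/14 factors).
#'
#' @param path Path to a vocabulary CSV. Defaults to the shipped fixture.
#' @return Named list of character vectors, one per vocabulary.
#' @export
load_vocabularies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabularies.csv", package = "painvol")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(tab), c("vocabulary", "token")))
  vocab <- split(tab$token, factor(tab$vocabulary, levels = unique(tab$vocabulary)))
  missing <- setdiff(names(VOCAB_SIZES), names(vocab))
  if (length(missing) > 0) {
    stop("vocabulary file is missing: ", paste(missing, collapse = ", "))
  }
  vocab <- vocab[names(VOCAB_SIZES)]
  sizes <- vapply(vocab, length, integer(1))
  bad <- sizes != VOCAB_SIZES
  if (any(bad)) {
    stop("vocabulary size mismatch: ",
         paste(sprintf("%s has %d tokens, expected %d", names(sizes)[bad],
                       sizes[bad], VOCAB_SIZES[bad]), collapse = "; "))
  }
  dup <- vapply(vocab, anyDuplicated, integer(1)) > 0
  if (any(dup)) stop("duplicate tokens in: ", paste(names(vocab)[dup], collapse = ", "))
  for (tok in NEUROPATHIC_CHARACTERISTICS) {
    if (!tok %in% vocab$characteristics) stop("characteristics vocabulary lacks '", tok, "'")
  }
  if (!NEUROPATHIC_AGGRAVATING %in% vocab$aggravating ||
      !all(MENTAL_HEALTH_AGGRAVATING %in% vocab$aggravating)) {
    stop("aggravating vocabulary lacks a token required by the composite flags")
  }
  if (!all(MENTAL_HEALTH_SYMPTOMS %in% vocab$symptoms)) {
    stop("symptoms vocabulary lacks 'anxiety'/'depression'")
  }
  vocab
}

#' @keywords internal
sanitize_token <- function(x) {
  gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(x)))
}
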