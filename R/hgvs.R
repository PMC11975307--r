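# Lightweight HGVS handling for protein-level (p.) and simple coding (c.)
# variant descriptions. Protein notation is canonicalized to three-letter
# amino-acid codes; one-letter input is normalized on the way in.

aa_three <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)
aa_one_to_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter", X = "Ter"
)

re_p3 <- "^p\\.\\(?([A-Z][a-z]{2})(\\d+)(=|[A-Z][a-z]{2})\\)?$"
re_p1 <- "^p\\.\\(?([ARNDCQEGHILKMFPSTWYV])(\\d+)(=|[ARNDCQEGHILKMFPSTWYVX*])\\)?$"
re_c_splice <- "^c\\.(\\d+)([+-]\\d+)([ACGT])>([ACGT])$"
re_c_coding <- "^c\\.(\\d+)([ACGT])>([ACGT])$"

#' Parse an HGVS-style variant string
#'
#' Accepts protein-level substitutions in three-letter (`p.Arg175His`) or
#' one-letter (`p.R175H`) notation, synonymous shorthand (`p.Ser215=` or
#' `p.Ser215Ser`), stop gains (`Ter`, `*`, `X`), and simple coding-level
#' single-nucleotide notation (`c.375+2T>C`, `c.215A>G`). One-letter amino
#' acids are normalized to three-letter codes.
#'
#' @param variant_id Character vector of variant strings.
#' @return A tibble with columns `input`, `variant`, (the normalized
#'   identifier), `consequence`, and `position` (1-based residue index for
#'   protein variants, coding base for nucleotide variants).
#' @examples
#' parse_variant(c("p.Arg175His", "p.S215=", "c.375+2T>C"))
#' @export
parse_variant <- function(variant_id) {
  stopifnot(is.character(variant_id))
  rows <- lapply(variant_id, parse_variant_one)
  dplyr::bind_rows(rows)
}

parse_variant_one <- function(v) {
  stopifnot(length(v) == 1L)
  v0 <- trimws(v)
  if (grepl(re_p3, v0)) {
    m <- regmatches(v0, regexec(re_p3, v0))[[1]]
    ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
    if (!(ref %in% aa_three)) {
      abort(paste0("unknown amino-acid code '", ref, "' in '", v, "'"))
    }
    if (alt != "=" && alt != "Ter" && !(alt %in% aa_three)) {
      abort(paste0("unknown amino-acid code '", alt, "' in '", v, "'"))
    }
    if (alt == "=") alt <- ref
  } else if (grepl(re_p1, v0)) {
    m <- regmatches(v0, regexec(re_p1, v0))[[1]]
    ref <- unname(aa_one_to_three[m[2]])
    pos <- as.integer(m[3])
    alt <- if (m[4] == "=") ref else unname(aa_one_to_three[m[4]])
    if (is.na(ref) || is.na(alt)) {
      abort(paste0("cannot normalize one-letter notation '", v, "'"))
    }
  } else if (grepl(re_c_splice, v0)) {
    m <- regmatches(v0, regexec(re_c_splice, v0))[[1]]
    return(tibble(
      input = v, variant = v0, consequence = "splice_candidate",
      position = as.integer(m[2])
    ))
  } else if (grepl(re_c_coding, v0)) {
    m <- regmatches(v0, regexec(re_c_coding, v0))[[1]]
    return(tibble(
      input = v, variant = v0, consequence = "other",
      position = as.integer(m[2])
    ))
  } else {
    abort(paste0("unparseable variant string: '", v, "'"),
      class = "mavemeld_parse_error"
    )
  }
  if (pos < 1L) abort(paste0("residue position must be >= 1 in '", v, "'"))
  if (ref == "Ter") {
    abort(paste0("ambiguous notation (reference is a stop) in '", v, "'"))
  }
  cons <- if (alt == "Ter") {
    "nonsense"
  } else if (alt == ref) {
    "synonymous"
  } else {
    "missense"
  }
  tibble(
    input = v, variant = paste0("p.", ref, pos, alt),
    consequence = cons, position = pos
  )
}

#' Classify the molecular consequence of a variant string
#'
#' @param variant_id Character vector of HGVS-style variant strings.
#' @return Character vector with values in `missense`, `synonymous`,
#'   `nonsense`, `splice_candidate`, `other`.
#' @examples
#' classify_consequence(c("p.Ser215Ser", "p.Arg196Ter", "c.375+2T>C"))
#' @export
classify_consequence <- function(variant_id) {
  parse_variant(variant_id)$consequence
}

#' Normalize variant identifiers to canonical three-letter p. notation
#'
#' @inheritParams classify_consequence
#' @return Character vector of normalized identifiers; coding-level (`c.`)
#'   strings are returned unchanged.
#' @export
normalize_variant <- function(variant_id) {
  parse_variant(variant_id)$variant
}
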