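#' The mutation class set
#'
#' Pyrimidine-normalized single-nucleotide classes plus the CpG transition
#' class and a pooled indel class, in conventional spectrum order.
#'
#' @return character vector of class labels.
#' @export
mutation_classes <- function() {
  c("C>A", "C>G", "C>T", "CpG>TpG", "T>A", "T>C", "T>G", "indel")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify a mutation into its spectrum class
#'
#' SNVs are normalized to a pyrimidine reference base (purine-reference
#' substitutions are mapped through the reverse complement, together with
#' their trinucleotide context), and a C>T change in a CG dinucleotide
#' context is assigned the `CpG>TpG` class. Any length-changing allele pair
#' is `indel`.
#'
#' @param ref,alt allele strings.
#' @param context trinucleotide reference context centered on the variant
#'   position (required for SNVs; its center must equal `ref`).
#' @return one of [mutation_classes()]. Vectorized over its arguments.
#' @export
classify_mutation <- function(ref, alt, context = NA_character_) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- character(n)
  is_indel <- nchar(ref) != nchar(alt) | nchar(ref) > 1
  out[is_indel] <- "indel"
  snv <- which(!is_indel)
  if (length(snv)) {
    r <- ref[snv]; a <- alt[snv]; ctx <- context[snv]
    if (anyNA(ctx) || any(nchar(ctx) != 3)) {
      stop("SNV classification requires a 3-base context")
    }
    if (any(substr(ctx, 2, 2) != r)) {
      stop("context center does not match the reference allele")
    }
    pur <- r %in% c("A", "G")
    if (any(pur)) {
      r[pur] <- revcomp(r[pur])
      a[pur] <- revcomp(a[pur])
      ctx[pur] <- revcomp(ctx[pur])
    }
    cls <- paste0(r, ">", a)
    cls[cls == "C>T" & substr(ctx, 3, 3) == "G"] <- "CpG>TpG"
    out[snv] <- cls
  }
  if (!all(out %in% mutation_classes())) stop("unclassifiable allele pair")
  out
}
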