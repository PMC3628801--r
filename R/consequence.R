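#' Construct a transcript model
#'
#' A coding sequence (CDS) with an identifier: the substrate of coding
#' consequence annotation. The CDS must be a valid open reading frame —
#' length divisible by three, initiator ATG, exactly one stop codon, at the
#' end.
#'
#' @param transcript_id accession / identifier.
#' @param cds DNA string over ACGT.
#' @param gene_symbol optional gene symbol.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, cds, gene_symbol = NA_character_) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds))
    stop("CDS must contain only A/C/G/T", call. = FALSE)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length must be divisible by 3", call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG")
    stop("CDS must start with ATG", call. = FALSE)
  aa <- codon_translate(cds)
  n_codons <- nchar(cds) / 3L
  stops <- which(aa == "*")
  if (length(stops) != 1L || stops != n_codons)
    stop("CDS must have exactly one stop codon, at the end", call. = FALSE)
  structure(list(transcript_id = transcript_id, cds = cds,
                 gene_symbol = gene_symbol),
            class = "transcript_model")
}

## per-codon translation, standard code, '*' for stops, no truncation
codon_translate <- function(dna) {
  seqinr::translate(strsplit(tolower(dna), "")[[1L]])
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon (not
#' included in the return value) and a trailing partial codon is ignored.
#'
#' @param cds DNA string over ACGT, length >= 3.
#' @return Protein string in one-letter code.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds))
    stop("CDS must contain only A/C/G/T", call. = FALSE)
  if (nchar(cds) < 3L) stop("CDS must be at least one codon", call. = FALSE)
  aa <- codon_translate(substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L))
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Construct a coding variant (CDS coordinates)
#'
#' @param transcript_id transcript the `c.` position refers to.
#' @param c_position 1-based position within the CDS.
#' @param ref reference bases (empty string for a pure insertion).
#' @param alt alternate bases (empty string for a pure deletion).
#' @return Object of class `coding_variant`.
#' @export
coding_variant <- function(transcript_id, c_position, ref, alt) {
  if (!is_count(c_position) || c_position < 1)
    stop("c_position must be a positive integer", call. = FALSE)
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) == 0L && nchar(alt) == 0L)
    stop("ref and alt cannot both be empty", call. = FALSE)
  if ((nchar(ref) && !grepl("^[ACGT]+$", ref)) ||
      (nchar(alt) && !grepl("^[ACGT]+$", alt)))
    stop("alleles must be DNA strings over ACGT", call. = FALSE)
  structure(list(transcript_id = transcript_id,
                 c_position = as.integer(c_position), ref = ref, alt = alt),
            class = "coding_variant")
}

#' Construct a consequence call
#' @param hgvs_c,hgvs_p HGVS descriptions.
#' @param effect one of synonymous, missense, nonsense, frameshift, other.
#' @param wt_orf_codons,mut_orf_codons ORF lengths in amino acids, stop
#'   codon excluded on both sides.
#' @param no_stop TRUE when a frameshift reaches the CDS end without a new
#'   stop (reported as `fs*?`).
#' @return Object of class `consequence_call`.
#' @export
consequence_call <- function(hgvs_c, hgvs_p, effect, wt_orf_codons,
                             mut_orf_codons, no_stop = FALSE) {
  stopifnot(effect %in% c("synonymous", "missense", "nonsense",
                          "frameshift", "other"))
  structure(list(hgvs_c = hgvs_c, hgvs_p = hgvs_p, effect = effect,
                 wt_orf_codons = as.integer(wt_orf_codons),
                 mut_orf_codons = as.integer(mut_orf_codons),
                 no_stop = isTRUE(no_stop)),
            class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s | %s | %s (ORF %d -> %d aa)\n", x$hgvs_c, x$hgvs_p,
              x$effect, x$wt_orf_codons, x$mut_orf_codons))
  invisible(x)
}

## right-shift a deletion within repeated sequence (HGVS 3' rule)
normalize_del_3prime <- function(cds, pos, len) {
  n <- nchar(cds)
  while (pos + len <= n &&
         substr(cds, pos, pos) == substr(cds, pos + len, pos + len))
    pos <- pos + 1L
  pos
}

#' Annotate the coding consequence of a CDS variant
#'
#' Classifies a variant given in CDS coordinates against a transcript
#' model and produces HGVS `c.` / `p.` descriptions, the effect class and
#' the wildtype/mutant ORF lengths (amino acids, stop excluded).
#'
#' An SNV is compared in frame: synonymous, missense (`p.X123Y`) or
#' nonsense (`p.X123*`). A length change that is not a multiple of three is
#' a frameshift, reported as `p.<wt_aa><pos><new_aa>fs*<n>` where `pos` is
#' the first codon whose amino acid changes, `<new_aa>` its mutant residue
#' and `n` the position of the new stop counting that codon as 1 (so
#' `p.Q2798Rfs*3` places the stop at codon 2800 and leaves a 2,799-residue
#' protein). Deletions are 3'-normalized within repeated sequence before
#' naming, per the HGVS rule. In-frame indels are classed `other`. A
#' frameshift that reaches the end of the CDS without encountering a stop
#' is reported as `fs*?` with `no_stop = TRUE`.
#'
#' @param tm a [transcript_model()].
#' @param cv a [coding_variant()]; `ref`, when non-empty, must match the
#'   CDS at `c_position`.
#' @return A [consequence_call()].
#' @export
annotate_coding_variant <- function(tm, cv) {
  stopifnot(inherits(tm, "transcript_model"), inherits(cv, "coding_variant"))
  cds <- tm$cds
  n <- nchar(cds)
  pos <- cv$c_position
  if (pos > n)
    stop("variant position lies 3' of the stop codon (out of CDS)",
         call. = FALSE)
  if (nchar(cv$ref) &&
      substr(cds, pos, pos + nchar(cv$ref) - 1L) != cv$ref)
    stop(sprintf("ref allele '%s' does not match CDS at c.%d", cv$ref, pos),
         call. = FALSE)

  wt_aa <- codon_translate(cds)
  wt_orf <- length(wt_aa) - 1L            # terminal stop excluded

  ref <- cv$ref; alt <- cv$alt
  shift <- nchar(alt) - nchar(ref)

  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    if (ref == alt)
      return(consequence_call(sprintf("c.%d%s=", pos, ref), "p.(=)",
                              "synonymous", wt_orf, wt_orf))
    codon_i <- (pos - 1L) %/% 3L + 1L
    mut <- cds
    substr(mut, pos, pos) <- alt
    mut_codon_aa <- codon_translate(substr(mut, (codon_i - 1L) * 3L + 1L,
                                           codon_i * 3L))
    hgvs_c <- sprintf("c.%d%s>%s", pos, ref, alt)
    old <- wt_aa[codon_i]
    if (mut_codon_aa == old)
      return(consequence_call(hgvs_c, "p.(=)", "synonymous", wt_orf, wt_orf))
    if (mut_codon_aa == "*")
      return(consequence_call(hgvs_c, sprintf("p.%s%d*", old, codon_i),
                              "nonsense", wt_orf, codon_i - 1L))
    if (old == "*") {
      # stop-loss: read through into nothing (no 3' UTR modeled)
      return(consequence_call(hgvs_c, sprintf("p.*%d%sext*?", codon_i,
                                              mut_codon_aa),
                              "other", wt_orf, wt_orf))
    }
    return(consequence_call(hgvs_c,
                            sprintf("p.%s%d%s", old, codon_i, mut_codon_aa),
                            "missense", wt_orf, wt_orf))
  }

  # indel / MNV path
  if (shift == 0L) {
    hgvs_c <- sprintf("c.%d_%ddelins%s", pos, pos + nchar(ref) - 1L, alt)
    mut <- paste0(substr(cds, 1L, pos - 1L), alt,
                  substr(cds, pos + nchar(ref), n))
    return(indel_call(hgvs_c, "other", cds, mut, wt_aa, wt_orf))
  }

  if (shift < 0L && nchar(alt) == 0L) {          # pure deletion
    len <- nchar(ref)
    pos <- normalize_del_3prime(cds, pos, len)
    deleted <- substr(cds, pos, pos + len - 1L)
    hgvs_c <- if (len == 1L) sprintf("c.%ddel%s", pos, deleted)
              else sprintf("c.%d_%ddel", pos, pos + len - 1L)
    mut <- paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + len, n))
  } else if (shift > 0L && nchar(ref) == 0L) {   # pure insertion
    hgvs_c <- sprintf("c.%d_%dins%s", pos - 1L, pos, alt)
    mut <- paste0(substr(cds, 1L, pos - 1L), alt, substr(cds, pos, n))
  } else {                                       # deletion-insertion
    hgvs_c <- sprintf("c.%d_%ddelins%s", pos, pos + nchar(ref) - 1L, alt)
    mut <- paste0(substr(cds, 1L, pos - 1L), alt,
                  substr(cds, pos + nchar(ref), n))
  }

  effect <- if (abs(shift) %% 3L == 0L) "other" else "frameshift"
  indel_call(hgvs_c, effect, cds, mut, wt_aa, wt_orf)
}

## common protein-level naming for length-changing variants
indel_call <- function(hgvs_c, effect, cds, mut, wt_aa, wt_orf) {
  mut_aa <- codon_translate(substr(mut, 1L, nchar(mut) - nchar(mut) %% 3L))
  stop_i <- which(mut_aa == "*")
  mut_orf <- if (length(stop_i)) stop_i[1L] - 1L else length(mut_aa)
  no_stop <- length(stop_i) == 0L

  # first codon whose residue changes
  lim <- min(length(wt_aa), length(mut_aa))
  diff <- which(wt_aa[seq_len(lim)] != mut_aa[seq_len(lim)])
  p1 <- if (length(diff)) diff[1L] else lim + 1L

  if (effect != "frameshift") {
    hgvs_p <- if (p1 > lim) "p.(=)" else "p.?"
    return(consequence_call(hgvs_c, hgvs_p, effect, wt_orf, mut_orf))
  }

  if (p1 > length(mut_aa))
    return(consequence_call(hgvs_c, "p.?", "frameshift", wt_orf, mut_orf,
                            no_stop = no_stop))
  new_aa <- mut_aa[p1]
  old_aa <- if (p1 <= length(wt_aa)) wt_aa[p1] else "?"
  if (new_aa == "*")
    return(consequence_call(hgvs_c, sprintf("p.%s%d*", old_aa, p1),
                            "frameshift", wt_orf, p1 - 1L))
  star <- if (no_stop) "?" else as.character(stop_i[1L] - p1 + 1L)
  consequence_call(hgvs_c,
                   sprintf("p.%s%d%sfs*%s", old_aa, p1, new_aa, star),
                   "frameshift", wt_orf, mut_orf, no_stop = no_stop)
}

#' Summarize the truncation implied by a consequence call
#'
#' @param call a [consequence_call()] with a truncating effect (nonsense or
#'   frameshift) and `mut_orf_codons < wt_orf_codons`.
#' @return list with `delta_codons` (wildtype minus mutant ORF length) and
#'   `fraction_lost`.
#' @export
truncation_summary <- function(call) {
  stopifnot(inherits(call, "consequence_call"))
  if (!call$effect %in% c("nonsense", "frameshift") ||
      call$mut_orf_codons >= call$wt_orf_codons)
    stop("truncation summary requires a truncating consequence",
         call. = FALSE)
  delta <- call$wt_orf_codons - call$mut_orf_codons
  list(delta_codons = delta,
       fraction_lost = delta / call$wt_orf_codons)
}
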