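#' Global pairwise nucleotide identity
#'
#' Needleman-Wunsch global alignment with free end gaps (match +1,
#' mismatch -1, linear gap cost 2 per position). Identity is the number of
#' identically matching columns divided by the total alignment span,
#' counting terminal overhangs as gap columns, so that e.g. "ACGT" vs
#' "ACG" gives 3/4. For equal-length substitution-only pairs the alignment
#' is gap-free and identity reduces to 1 - Hamming distance / length.
#' `N` bases count as mismatches.
#'
#' @param a,b Nucleotide sequences (character scalars over A/C/G/T/N).
#' @return Identity fraction in [0, 1]; 1.0 iff the sequences are identical.
#' @export
global_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != 1L || length(b) != 1L || nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty character scalars")
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b))
    stop("sequences may only contain A, C, G, T, N")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == pb & pa %in% c("A", "C", "G", "T"))
  p_rng <- c(Biostrings::start(Biostrings::pattern(aln)),
             Biostrings::end(Biostrings::pattern(aln)))
  s_rng <- c(Biostrings::start(Biostrings::subject(aln)),
             Biostrings::end(Biostrings::subject(aln)))
  left <- max(p_rng[1L] - 1L, s_rng[1L] - 1L)
  right <- max(nchar(a) - p_rng[2L], nchar(b) - s_rng[2L])
  columns <- length(pa) + left + right
  matches / columns
}

#' Species assignment configuration for type-strain disambiguation
#'
#' @param references Named character vector mapping species name to its
#'   type-strain 16S sequence; at least two references are required for
#'   disambiguation between closely related species.
#' @param threshold Identity fraction an ASV must strictly exceed to be
#'   assigned to a species (default 0.9980).
#' @return An `assignment_config` object.
#' @export
assignment_config <- function(references, threshold = 0.9980) {
  if (is.null(names(references)) || any(names(references) == ""))
    stop("references must be a named character vector")
  if (length(references) < 2L)
    stop("disambiguation requires at least 2 reference sequences")
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  structure(list(references = references, threshold = threshold),
            class = "assignment_config")
}

#' Assign an ASV to a species by the strict identity-threshold rule
#'
#' An ASV is assigned to a reference species only when its identity to that
#' species' type strain strictly exceeds the threshold and to no other
#' reference; otherwise it receives the joined intermediate label (e.g.
#' "lactis/cremoris"). Identity above the threshold to more than one
#' reference also yields the intermediate label, with a tie warning flag.
#'
#' @param asv_seq ASV nucleotide sequence.
#' @param config An [assignment_config()].
#' @return A `species_call`: list with `label`, `identities` (named, one
#'   per reference) and `tie` (logical).
#' @export
assign_species <- function(asv_seq, config) {
  stopifnot(inherits(config, "assignment_config"))
  refs <- config$references
  identities <- vapply(refs, function(r) global_identity(asv_seq, r), 0)
  above <- identities > config$threshold     # strictly above
  intermediate <- paste(names(refs), collapse = "/")
  if (sum(above) == 1L) {
    label <- names(refs)[above]; tie <- FALSE
  } else {
    label <- intermediate
    tie <- sum(above) > 1L
    if (tie) warning("ASV exceeds the identity threshold to ",
                     sum(above), " references; labelled intermediate")
  }
  structure(list(label = label, identities = identities, tie = tie),
            class = "species_call")
}

#' Assign many ASVs against a reference set
#'
#' @param asv_seqs Named character vector of ASV sequences.
#' @param config An [assignment_config()].
#' @return data.frame with `asv_id`, one identity column per reference,
#'   `label`, `tie`.
#' @export
assign_species_table <- function(asv_seqs, config) {
  calls <- lapply(asv_seqs, assign_species, config = config)
  ident <- do.call(rbind, lapply(calls, `[[`, "identities"))
  out <- data.frame(asv_id = names(asv_seqs), ident,
                    label = vapply(calls, `[[`, "", "label"),
                    tie = vapply(calls, `[[`, NA, "tie"),
                    row.names = NULL, check.names = FALSE)
  out
}
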