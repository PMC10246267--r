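#' Map residue positions between S6 segments by global alignment
#'
#' Aligns a reference S6 sequence against a query (Needleman-Wunsch via
#' `Biostrings::pairwiseAlignment`, BLOSUM62, affine gaps) and carries
#' reference residue positions through the aligned columns. Sequences
#' may be given as strings, `AAString`s, or paths to FASTA files; a
#' FASTA header token `start=N` (or a `start` argument) anchors the
#' absolute numbering of the first residue. Reference positions that
#' align onto a gap are reported as unmapped (`NA`).
#'
#' @param query,reference sequences (string, `AAString`, or FASTA path)
#' @param reference_positions integer vector of absolute residue numbers
#'   in the reference
#' @param query_start,reference_start absolute number of each sequence's
#'   first residue (default: `start=` tag in the FASTA header, else 1)
#' @param gap_opening,gap_extension affine gap penalties
#' @param min_identity identity (fraction) below which a warning flag is
#'   set on the result
#' @return data.frame `reference_pos`, `reference_aa`, `query_pos`
#'   (NA if unmapped), `query_aa`; attributes `identity` and
#'   `low_identity_warning`
#' @examples
#' map_residues("MKTAYIAKQRQISFVKSH", "MKTAYIAKQRQISFVKSH", c(3, 7))
#' @export
map_residues <- function(query, reference, reference_positions,
                         query_start = NULL, reference_start = NULL,
                         gap_opening = 10, gap_extension = 1,
                         min_identity = 0.30) {
  qs <- .load_seq(query);  rs <- .load_seq(reference)
  q_start <- query_start %||% qs$start
  r_start <- reference_start %||% rs$start
  if (nchar(qs$seq) < 15 || nchar(rs$seq) < 15)
    .nav_stop("sequences must be at least 15 residues",
              "navgate_bad_input")
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rs$seq), Biostrings::AAString(qs$seq),
    type = "global", substitutionMatrix = get("BLOSUM62", data_env),
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  idt <- Biostrings::pid(aln) / 100
  ri <- qi <- 0L
  map <- integer(0); qaa <- character(0)
  ref_abs <- integer(0)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ri <- ri + 1L
    if (sub[k] != "-") qi <- qi + 1L
    if (pat[k] != "-") {
      ref_abs <- c(ref_abs, r_start + ri - 1L)
      map <- c(map, if (sub[k] != "-") q_start + qi - 1L else NA_integer_)
      qaa <- c(qaa, if (sub[k] != "-") sub[k] else NA_character_)
    }
  }
  idx <- match(reference_positions, ref_abs)
  if (anyNA(idx))
    .nav_stop("reference positions outside the reference sequence",
              "navgate_bad_input")
  out <- data.frame(reference_pos = reference_positions,
                    reference_aa = strsplit(rs$seq, "")[[1]][
                      reference_positions - r_start + 1L],
                    query_pos = map[idx],
                    query_aa = qaa[idx])
  attr(out, "identity") <- idt
  attr(out, "low_identity_warning") <- idt < min_identity
  if (idt < min_identity)
    warning(sprintf("alignment identity %.0f%% below %.0f%%; mapping unreliable",
                    100 * idt, 100 * min_identity))
  out
}

.load_seq <- function(x) {
  if (inherits(x, "AAString"))
    return(list(seq = as.character(x), start = 1L))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      grepl("\\.(fa|fasta|faa)$", x, ignore.case = TRUE)) {
    ss <- Biostrings::readAAStringSet(x)
    hdr <- names(ss)[1]
    m <- regmatches(hdr, regexpr("start=([0-9]+)", hdr))
    st <- if (length(m)) as.integer(sub("start=", "", m)) else 1L
    return(list(seq = as.character(ss[[1]]), start = st))
  }
  if (is.character(x) && length(x) == 1)
    return(list(seq = toupper(x), start = 1L))
  .nav_stop("cannot interpret sequence input", "navgate_bad_input")
}
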