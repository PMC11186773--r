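#' Reference amplicon with a coding-sequence anchor
#'
#' Builds the coordinate frame every other stage consumes: an amplicon
#' sequence plus an anchor tying one amplicon position to a protein residue
#' number, from which codon boundaries are tiled in both directions.
#'
#' All coordinates in this package are 1-based, closed intervals.
#'
#' @param name Identifier for the amplicon.
#' @param sequence Uppercase DNA string (A/C/G/T only).
#' @param anchor_pos 1-based amplicon position of the anchor base.
#' @param anchor_residue Protein residue number whose codon contains the
#'   anchor base.
#' @param frame_offset 0, 1 or 2: the anchor base is the
#'   `frame_offset + 1`-th base of that codon (reading in CDS orientation).
#' @param cds_strand `"+"` if the coding sequence reads along the amplicon,
#'   `"-"` if it reads along the reverse complement.
#' @return An object of class `amplicon_ref`.
#' @examples
#' amp <- amplicon_ref("toy", "ATGAAAGGG", 1, 1, 0)
#' @export
amplicon_ref <- function(name, sequence, anchor_pos, anchor_residue,
                         frame_offset = 0L, cds_strand = "+") {
  assert_dna(sequence, "amplicon sequence")
  stopifnot(is.character(name), length(name) == 1L)
  anchor_pos <- as.integer(anchor_pos)
  anchor_residue <- as.integer(anchor_residue)
  frame_offset <- as.integer(frame_offset)
  if (anchor_pos < 1L || anchor_pos > nchar(sequence))
    stop("FrameError: cds anchor position ", anchor_pos,
         " lies outside the amplicon (length ", nchar(sequence), ")",
         call. = FALSE)
  if (!frame_offset %in% 0:2)
    stop("FrameError: frame_offset must be 0, 1 or 2", call. = FALSE)
  cds_strand <- match.arg(cds_strand, c("+", "-"))
  structure(
    list(name = name, sequence = sequence, anchor_pos = anchor_pos,
         anchor_residue = anchor_residue, frame_offset = frame_offset,
         cds_strand = cds_strand),
    class = "amplicon_ref")
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("<amplicon_ref> %s: %d nt, CDS anchor pos %d = residue %d (frame %d, strand %s)\n",
              x$name, nchar(x$sequence), x$anchor_pos, x$anchor_residue,
              x$frame_offset, x$cds_strand))
  invisible(x)
}

#' Read amplicon references from a FASTA file
#'
#' Each record becomes an `amplicon_ref`. The CDS anchor is not encoded in
#' FASTA; supply it per record (recycled if length 1).
#'
#' @param path FASTA file (single- or multi-record).
#' @inheritParams amplicon_ref
#' @return A named list of `amplicon_ref` objects.
#' @export
read_amplicon_fasta <- function(path, anchor_pos, anchor_residue,
                                frame_offset = 0L, cds_strand = "+") {
  seqs <- Biostrings::readDNAStringSet(path)
  n <- length(seqs)
  rec <- function(v) rep_len(v, n)
  out <- Map(amplicon_ref,
             name = names(seqs),
             sequence = as.character(seqs),
             anchor_pos = rec(anchor_pos),
             anchor_residue = rec(anchor_residue),
             frame_offset = rec(frame_offset),
             cds_strand = rec(cds_strand))
  stats::setNames(out, names(seqs))
}

#' Read a guide list from a two-column TSV (name, sequence)
#'
#' @param path TSV file with columns `name` and `sequence` (header optional
#'   if the first field is not a valid DNA string).
#' @return Named character vector of guide sequences.
#' @export
read_guides_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("guide TSV needs two columns: name, sequence")
  stats::setNames(toupper(df[[2L]]), df[[1L]])
}

#' Locate a 20-nt protospacer on an amplicon
#'
#' Searches both strands for a unique exact placement of the guide. The
#' returned object carries the protospacer coordinate frame: positions
#' 1--20 run 5' to 3' along the protospacer strand, position 20 is
#' PAM-proximal, and the PAM occupies positions 21--23.
#'
#' The PAM is recorded for reporting but never used as a filter (near-PAMless
#' editors are in scope).
#'
#' @param amplicon An [amplicon_ref()].
#' @param guide 20-nt DNA guide (protospacer) sequence.
#' @return An object of class `protospacer` with fields `guide_seq`,
#'   `start` (leftmost amplicon coordinate of the 20-nt footprint),
#'   `strand` (+/- relative to the amplicon) and `pam_seq` (3 nt in
#'   protospacer orientation, `NA` if truncated by the amplicon edge).
#' @export
locate_protospacer <- function(amplicon, guide) {
  stopifnot(inherits(amplicon, "amplicon_ref"))
  guide <- toupper(guide)
  assert_dna(guide, "guide")
  if (nchar(guide) != 20L)
    stop("guide must be exactly 20 nt, got ", nchar(guide), call. = FALSE)
  seq <- amplicon$sequence
  find_all <- function(pat) {
    hits <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits)
  }
  fwd <- find_all(guide)
  rev <- find_all(revcomp(guide))
  n_hits <- length(fwd) + length(rev)
  if (n_hits == 0L)
    stop("NotFound: guide does not match amplicon '", amplicon$name,
         "' on either strand", call. = FALSE)
  if (n_hits > 1L)
    stop("Ambiguous: guide matches amplicon '", amplicon$name, "' at ",
         n_hits, " loci across both strands", call. = FALSE)
  strand <- if (length(fwd)) "+" else "-"
  start <- if (length(fwd)) fwd else rev
  pam_pos <- if (strand == "+") (start + 20L):(start + 22L)
             else (start - 1L):(start - 3L)
  pam <- NA_character_
  if (all(pam_pos >= 1L & pam_pos <= nchar(seq))) {
    bases <- vapply(pam_pos, function(p) substr(seq, p, p), character(1))
    if (strand == "-") bases <- complement_base(bases)
    pam <- paste(bases, collapse = "")
  }
  structure(list(guide_seq = guide, start = start, strand = strand,
                 pam_seq = pam, amplicon_name = amplicon$name),
            class = "protospacer")
}

#' @export
print.protospacer <- function(x, ...) {
  cat(sprintf("<protospacer> %s @ %s:%d (%s), PAM %s\n",
              x$guide_seq, x$amplicon_name, x$start, x$strand, x$pam_seq))
  invisible(x)
}

#' Map protospacer positions to amplicon coordinates
#'
#' @param proto A [locate_protospacer()] result.
#' @param pos Integer vector of protospacer positions (1 = 5' end of the
#'   protospacer, 20 = PAM-proximal; 21--23 address the PAM).
#' @return Integer vector of 1-based amplicon positions.
#' @export
proto_to_amp <- function(proto, pos) {
  stopifnot(inherits(proto, "protospacer"))
  pos <- as.integer(pos)
  if (proto$strand == "+") proto$start + pos - 1L else proto$start + 20L - pos
}

#' Window specification relative to a protospacer
#'
#' Windows are defined by a centre offset relative to the protospacer 3' end
#' (position 20) and a size in nucleotides. The default quantification
#' window (centre -10, size 15) resolves to protospacer positions 3--17.
#'
#' @param center_offset Offset in nt of the window centre from protospacer
#'   position 20 (e.g. -10 places the centre at position 10).
#' @param size Window width in nt (>= 1). For even sizes the extra base is
#'   placed 3' of the centre (floor/ceil split).
#' @param kind One of `"quantification"`, `"editing"`, `"offtarget-scoring"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(center_offset = -10L, size = 15L,
                        kind = c("quantification", "editing",
                                 "offtarget-scoring")) {
  size <- as.integer(size)
  if (size < 1L) stop("window size must be >= 1", call. = FALSE)
  structure(list(center_offset = as.integer(center_offset), size = size,
                 kind = match.arg(kind)),
            class = "window_spec")
}

#' Resolve a window spec to amplicon coordinates
#'
#' The window centre sits at protospacer position `20 + center_offset`; the
#' window covers `[centre - floor((size-1)/2), centre + ceil((size-1)/2)]`
#' in protospacer coordinates, then maps to amplicon coordinates respecting
#' the protospacer strand.
#'
#' @param spec A [window_spec()].
#' @param proto A [locate_protospacer()] result.
#' @param amplicon The [amplicon_ref()] the protospacer was located on.
#' @return An object of class `amplicon_window`: fields `start`, `end`
#'   (amplicon coordinates, closed), `proto_start`, `proto_end`
#'   (protospacer coordinates) and `strand`.
#' @export
resolve_window <- function(spec, proto, amplicon) {
  stopifnot(inherits(spec, "window_spec"), inherits(proto, "protospacer"),
            inherits(amplicon, "amplicon_ref"))
  center <- 20L + spec$center_offset
  lo <- center - (spec$size - 1L) %/% 2L
  hi <- center + (spec$size - 1L + 1L) %/% 2L  # ceil((size-1)/2)
  amp <- proto_to_amp(proto, c(lo, hi))
  start <- min(amp); end <- max(amp)
  if (start < 1L || end > nchar(amplicon$sequence))
    stop("OutOfBounds: resolved window [", start, ",", end,
         "] exceeds amplicon '", amplicon$name, "' (length ",
         nchar(amplicon$sequence), ")", call. = FALSE)
  structure(list(start = start, end = end, proto_start = lo, proto_end = hi,
                 strand = proto$strand, kind = spec$kind),
            class = "amplicon_window")
}

#' Build the residue/codon coordinate map for an amplicon
#'
#' Tiles codons outward from the CDS anchor over every fully-contained codon
#' and records, for each amplicon position in the CDS span, the protein
#' residue number and the codon position (1--3, in CDS orientation). For a
#' minus-strand CDS, codon positions run along decreasing amplicon
#' coordinates and bases are complemented at translation time.
#'
#' @param amplicon An [amplicon_ref()].
#' @return An object of class `codon_map`: a data.frame with columns
#'   `amp_pos`, `residue`, `codon_pos`, plus attributes `cds_strand` and
#'   `residues` (the covered residue range).
#' @export
build_codon_map <- function(amplicon) {
  stopifnot(inherits(amplicon, "amplicon_ref"))
  L <- nchar(amplicon$sequence)
  dir <- if (amplicon$cds_strand == "+") 1L else -1L
  # amplicon coordinate of codon position 1 of the anchor residue
  first <- amplicon$anchor_pos - dir * amplicon$frame_offset
  if (first < 1L || first > L)
    stop("FrameError: anchor frame places codon start outside the amplicon",
         call. = FALSE)
  codon_start <- function(r) first + dir * 3L * (r - amplicon$anchor_residue)
  codon_ok <- function(st) {
    en <- st + dir * 2L
    min(st, en) >= 1L && max(st, en) <= L
  }
  r_lo <- amplicon$anchor_residue
  while (codon_ok(codon_start(r_lo - 1L))) r_lo <- r_lo - 1L
  r_hi <- amplicon$anchor_residue
  while (codon_ok(codon_start(r_hi + 1L))) r_hi <- r_hi + 1L
  if (!codon_ok(codon_start(r_lo)))
    stop("FrameError: anchor residue codon is not fully inside the amplicon",
         call. = FALSE)
  residues <- r_lo:r_hi
  df <- do.call(rbind, lapply(residues, function(r) {
    st <- codon_start(r)
    data.frame(amp_pos = st + dir * (0:2), residue = r, codon_pos = 1:3)
  }))
  if (anyDuplicated(df$amp_pos))
    stop("FrameError: codon tiling overlaps itself", call. = FALSE)
  structure(df, class = c("codon_map", "data.frame"),
            cds_strand = amplicon$cds_strand,
            residues = range(residues))
}

#' Amplicon positions of one residue's codon
#'
#' @param map A [build_codon_map()] result.
#' @param residue Protein residue number.
#' @return Integer vector of 3 amplicon positions in codon order
#'   (decreasing for a minus-strand CDS).
#' @export
residue_codon_positions <- function(map, residue) {
  rows <- map[map$residue == residue, , drop = FALSE]
  if (nrow(rows) != 3L)
    stop("residue ", residue, " is not covered by the codon map",
         call. = FALSE)
  rows$amp_pos[order(rows$codon_pos)]
}

# Reference codon (CDS orientation) of a residue.
codon_of <- function(amplicon, map, residue) {
  pos <- residue_codon_positions(map, residue)
  bases <- vapply(pos, function(p) substr(amplicon$sequence, p, p),
                  character(1))
  if (attr(map, "cds_strand") == "-") bases <- complement_base(bases)
  paste(bases, collapse = "")
}
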