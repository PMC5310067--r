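#' Length of a genomic region
#'
#' Coordinates throughout the package are 1-based and inclusive at both
#' ends, so an amplicon's length is `end - start + 1`.
#'
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @return Integer vector of region lengths in bp.
#' @examples
#' region_length(117479627, 117479759)  # 133
#' @export
region_length <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end))) stop("non-numeric region coordinates")
  if (any(end < start)) stop("invalid region: start > end")
  as.integer(end - start + 1)
}

#' Parse a "chrN:start-end" coordinate string
#'
#' Commas used as thousands separators are tolerated.
#'
#' @param x Character vector of coordinate strings.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("unparseable region string: ", x[bad][1])
  data.frame(
    chrom = vapply(m, `[`, character(1), 2),
    start = as.numeric(vapply(m, `[`, character(1), 3)),
    end = as.numeric(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Locate CpG dinucleotides in a sequence
#'
#' @param sequence A single DNA string over A, C, G, T (case-insensitive).
#' @return Integer vector of 1-based offsets where "CG" starts, in 5'->3'
#'   order. CpG sites in all package outputs are numbered by their ordinal
#'   rank in this vector.
#' @examples
#' find_cpgs("ACGTCG")  # c(2, 5)
#' @export
find_cpgs <- function(sequence) {
  stopifnot(length(sequence) == 1)
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT characters")
  hits <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' In-silico bisulfite conversion of an amplicon strand
#'
#' Produces the converted reference used for bisulfite-aware read matching
#' and methylation calling. On the chosen strand, every cytosine outside a
#' CpG context is deaminated to T; CpG cytosines are left ambiguous (read C
#' when methylated, T when unmethylated).
#'
#' @param sequence Uppercase DNA string (the top/genomic strand).
#' @param strand `"top"` converts the sequence as given; `"bottom"` converts
#'   its reverse complement.
#' @return An object of class `bisulfite_reference`: a list with the
#'   oriented original `sequence`, the `converted` sequence (non-CpG C -> T,
#'   CpG C kept as C), `cpg_positions` (ambiguous sites), and
#'   `converted_positions` (non-CpG cytosines, the conversion-rate
#'   informative sites).
#' @export
bisulfite_convert <- function(sequence, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  s <- toupper(sequence)
  if (strand == "bottom") s <- reverse_complement(s)
  cpg <- find_cpgs(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  c_pos <- which(chars == "C")
  conv_pos <- setdiff(c_pos, cpg)
  converted <- chars
  converted[conv_pos] <- "T"
  structure(
    list(
      sequence = s,
      strand = strand,
      converted = paste(converted, collapse = ""),
      cpg_positions = cpg,
      converted_positions = conv_pos
    ),
    class = "bisulfite_reference"
  )
}

#' @export
print.bisulfite_reference <- function(x, ...) {
  chars <- strsplit(x$converted, "", fixed = TRUE)[[1]]
  chars[x$cpg_positions] <- "[C/T]"
  cat(sprintf("bisulfite_reference (%s strand): %s\n", x$strand,
              paste(chars, collapse = "")))
  cat(sprintf("  %d ambiguous CpG site(s), %d converted C\n",
              length(x$cpg_positions), length(x$converted_positions)))
  invisible(x)
}

#' Construct an amplicon panel
#'
#' @param regions data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `declared_n_cpg`, `declared_size`.
#' @param sequences Optional named character vector of amplicon sequences
#'   (names = gene symbols).
#' @param assembly Genome build label.
#' @return An `amplicon_panel`: the regions data.frame with a `sequence`
#'   column and attributes, validated for internal consistency (coordinates,
#'   sequence alphabet, sequence length vs region length where supplied).
#' @export
amplicon_panel <- function(regions, sequences = NULL, assembly = "GRCh38") {
  need <- c("gene", "chrom", "start", "end", "declared_n_cpg", "declared_size")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("panel regions missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(regions) == 0) stop("empty panel")
  if (anyDuplicated(regions$gene)) stop("duplicate gene symbols in panel")
  region_length(regions$start, regions$end)  # validates start <= end
  regions$sequence <- NA_character_
  if (!is.null(sequences)) {
    idx <- match(regions$gene, names(sequences))
    regions$sequence <- toupper(unname(sequences[idx]))
    has <- !is.na(regions$sequence)
    lens <- nchar(regions$sequence[has])
    rl <- region_length(regions$start[has], regions$end[has])
    if (any(lens != rl))
      stop("sequence length differs from region length for: ",
           paste(regions$gene[has][lens != rl], collapse = ", "))
    for (s in regions$sequence[has]) find_cpgs(s)  # alphabet check
  }
  structure(regions, assembly = assembly,
            class = c("amplicon_panel", "data.frame"))
}

#' Number of CpG sites per amplicon
#' @param panel An `amplicon_panel` with sequences.
#' @return Named integer vector of computed CpG counts.
#' @export
panel_n_cpg <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  setNames(vapply(panel$sequence, function(s) {
    if (is.na(s)) NA_integer_ else length(find_cpgs(s))
  }, integer(1), USE.NAMES = FALSE), panel$gene)
}

#' Validate a panel against its declared metadata
#'
#' Recomputes each amplicon's length from its coordinates and its CpG count
#' from its sequence, and flags disagreement with the declared values.
#'
#' @param panel An `amplicon_panel`.
#' @return data.frame with one row per checked field per amplicon: `gene`,
#'   `field` ("size" or "n_cpg"), `declared`, `computed`, `ok`. Class
#'   `panel_validation` with an attached `n_discrepancies` attribute.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  if (nrow(panel) == 0) stop("empty panel")
  size <- region_length(panel$start, panel$end)
  ncpg <- panel_n_cpg(panel)
  rep <- rbind(
    data.frame(gene = panel$gene, field = "size",
               declared = panel$declared_size, computed = size),
    data.frame(gene = panel$gene, field = "n_cpg",
               declared = panel$declared_n_cpg, computed = unname(ncpg))
  )
  rep$ok <- !is.na(rep$computed) & rep$declared == rep$computed
  rep <- rep[order(rep$gene, rep$field), ]
  rownames(rep) <- NULL
  structure(rep, n_discrepancies = sum(!rep$ok, na.rm = TRUE),
            class = c("panel_validation", "data.frame"))
}

#' Write a panel as FASTA plus TSV sidecar
#' @param panel An `amplicon_panel` with sequences.
#' @param fasta,tsv Output paths.
#' @export
write_panel <- function(panel, fasta, tsv) {
  stopifnot(inherits(panel, "amplicon_panel"))
  seqs <- Biostrings::DNAStringSet(panel$sequence)
  names(seqs) <- sprintf("%s %s:%d-%d", panel$gene, panel$chrom,
                         panel$start, panel$end)
  Biostrings::writeXStringSet(seqs, fasta)
  write_tsv(as.data.frame(panel)[, c("gene", "chrom", "start", "end",
                                     "declared_n_cpg", "declared_size")], tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read a panel from FASTA plus TSV sidecar
#' @param fasta FASTA of amplicon sequences, headers "GENE chrom:start-end".
#' @param tsv Sidecar TSV with declared metadata.
#' @param assembly Genome build label.
#' @return An `amplicon_panel`.
#' @export
read_panel <- function(fasta, tsv, assembly = "GRCh38") {
  meta <- read_tsv(tsv)
  seqs <- Biostrings::readDNAStringSet(fasta)
  genes <- sub(" .*$", "", names(seqs))
  amplicon_panel(meta, setNames(as.character(seqs), genes),
                 assembly = assembly)
}

#' The packaged 14-gene cystic fibrosis modifier panel
#'
#' The CFTR + 13 lung-modifier-gene amplicon panel: GRCh38 coordinates,
#' declared CpG counts (total 194) and amplicon sizes (133-260 bp). The
#' printed EDNRA end coordinate is truncated in the source table; the
#' packaged value (147,481,216) is the unique completion consistent with the
#' declared 260 bp, and [validate_panel()] confirms it.
#'
#' Amplicon sequences are not published, so the packaged FASTA contains
#' SYNTHETIC sequences generated to match each amplicon's declared length
#' and CpG count exactly (see `inst/extdata/cf_panel_synthetic.fasta`).
#' They support simulation and pipeline testing, not genomic lookup.
#'
#' @param sequences If `TRUE` (default) attach the synthetic sequences.
#' @return An `amplicon_panel` of 14 amplicons.
#' @export
cf_panel <- function(sequences = TRUE) {
  meta <- read_tsv(system.file("extdata", "cf_panel.tsv",
                               package = "methpanel", mustWork = TRUE))
  seqs <- NULL
  if (sequences) {
    fa <- Biostrings::readDNAStringSet(
      system.file("extdata", "cf_panel_synthetic.fasta",
                  package = "methpanel", mustWork = TRUE))
    seqs <- setNames(as.character(fa), sub(" .*$", "", names(fa)))
  }
  amplicon_panel(meta, seqs)
}
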