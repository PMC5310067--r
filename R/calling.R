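#' Read a FASTQ file into a read table
#' @param path FASTQ path.
#' @return data.frame `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub(" .*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to at most one library by exact prefix match of its
#' multiplex identifier (MID) barcode, after skipping an optional fixed
#' adaptor. The barcode (and adaptor) are trimmed from retained reads.
#'
#' @param reads data.frame `read_id`, `sequence` (e.g. from [read_fastq()]).
#' @param sample_sheet data.frame with `library_id` and `barcode` columns;
#'   barcodes must be unique and of equal length.
#' @param adaptor_length Bases to skip before the barcode.
#' @return list: `reads` (read_id, library_id, sequence trimmed),
#'   `n_unassigned`, `counts` (reads per library).
#' @export
demultiplex <- function(reads, sample_sheet, adaptor_length = 0) {
  bc <- sample_sheet$barcode
  if (anyDuplicated(bc)) stop("duplicate barcodes in sample sheet")
  if (length(unique(nchar(bc))) > 1) stop("barcodes must have equal length")
  w <- nchar(bc[1])
  prefix <- substr(reads$sequence, adaptor_length + 1, adaptor_length + w)
  idx <- match(prefix, bc)
  assigned <- !is.na(idx)
  out <- data.frame(
    read_id = reads$read_id[assigned],
    library_id = sample_sheet$library_id[idx[assigned]],
    sequence = substr(reads$sequence[assigned], adaptor_length + w + 1,
                      nchar(reads$sequence[assigned])),
    stringsAsFactors = FALSE)
  counts <- table(factor(out$library_id, levels = sample_sheet$library_id))
  list(reads = out, n_unassigned = sum(!assigned),
       counts = as.data.frame(counts, responseName = "n_reads",
                              stringsAsFactors = FALSE))
}

# match patterns: original-strand characters; any original C (CpG or not)
# accepts C or T in a bisulfite read, everything else must match exactly
build_patterns <- function(panel) {
  pats <- list()
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene[i]
    for (strand in c("top", "bottom")) {
      ref <- bisulfite_convert(panel$sequence[i], strand)
      pats[[paste(g, strand)]] <- list(
        gene = g, strand = strand, ref = ref,
        chars = strsplit(ref$sequence, "", fixed = TRUE)[[1]])
    }
  }
  pats
}

mismatch_counts <- function(m, pat) {
  ref <- pat$chars
  isC <- ref == "C"
  neq <- m != ref                       # ref recycled down columns
  if (any(isC))
    neq[isC, ] <- m[isC, , drop = FALSE] != "C" &
                  m[isC, , drop = FALSE] != "T"
  colSums(neq)
}

#' Assign trimmed reads to panel amplicons
#'
#' Ungapped bisulfite-aware matching: a read (or its reverse complement) is
#' compared against each amplicon's top- and bottom-strand bisulfite
#' references; at positions where the reference strand carries a cytosine,
#' both C (unconverted/methylated) and T (converted) are accepted. The best
#' amplicon/strand/orientation is chosen by minimum mismatch count; reads
#' whose best mismatch fraction exceeds `max_mismatch_frac`, or whose
#' length matches no amplicon, are unassigned. Ties go to the first
#' amplicon in panel order and are counted.
#'
#' @param reads data.frame `read_id`, `sequence` (barcode-trimmed).
#' @param panel An `amplicon_panel` with sequences.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @return data.frame `read_id`, `gene`, `strand`, `orientation`,
#'   `mismatches`, `tied` (logical); unassigned reads have `gene = NA`.
#' @export
assign_to_amplicon <- function(reads, panel, max_mismatch_frac = 0.1) {
  stopifnot(inherits(panel, "amplicon_panel"))
  pats <- build_patterns(panel)
  res <- data.frame(read_id = reads$read_id, gene = NA_character_,
                    strand = NA_character_, orientation = NA_character_,
                    mismatches = NA_integer_, tied = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(res)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$sequence)))
  lens <- nchar(reads$sequence)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    cand <- Filter(function(p) length(p$chars) == L, pats)
    if (!length(cand)) next
    m_f <- seq_matrix(reads$sequence[sel])
    m_r <- seq_matrix(rc[sel])
    best <- rep(Inf, length(sel)); nbest <- integer(length(sel))
    bgene <- bstrand <- borient <- rep(NA_character_, length(sel))
    for (p in cand) {
      for (orient in c("forward", "reverse")) {
        mm <- mismatch_counts(if (orient == "forward") m_f else m_r, p)
        better <- mm < best
        tie <- mm == best & is.finite(best)
        nbest[tie] <- nbest[tie] + 1L
        nbest[better] <- 1L
        best[better] <- mm[better]
        bgene[better] <- p$gene
        bstrand[better] <- p$strand
        borient[better] <- orient
      }
    }
    ok <- best / L <= max_mismatch_frac
    res$gene[sel[ok]] <- bgene[ok]
    res$strand[sel[ok]] <- bstrand[ok]
    res$orientation[sel[ok]] <- borient[ok]
    res$mismatches[sel[ok]] <- as.integer(best[ok])
    res$tied[sel[ok]] <- nbest[ok] > 1L
  }
  res
}

#' Bisulfite conversion rate of aligned reads
#'
#' The conversion rate is the fraction of informative non-CpG cytosine
#' positions of the reference at which the read shows T (converted) rather
#' than C (unconverted). Positions showing any other base are ignored;
#' reads with zero informative positions get `NA` with a flag and are
#' retained, since the amplicons carry many non-CpG cytosines and the case
#' is pathological.
#'
#' @param sequences Character vector of reads oriented to the reference.
#' @param reference A `bisulfite_reference` (see [bisulfite_convert()]).
#' @return data.frame `conversion_rate`, `n_informative`, `no_evidence`.
#' @export
conversion_rate <- function(sequences, reference) {
  cp <- reference$converted_positions
  n <- length(sequences)
  if (!length(cp))
    return(data.frame(conversion_rate = rep(NA_real_, n),
                      n_informative = 0L, no_evidence = TRUE))
  m <- seq_matrix(sequences)[cp, , drop = FALSE]
  nT <- colSums(m == "T"); nC <- colSums(m == "C")
  inf <- nT + nC
  data.frame(conversion_rate = ifelse(inf > 0, nT / inf, NA_real_),
             n_informative = as.integer(inf), no_evidence = inf == 0)
}

#' Call per-CpG methylation states of aligned reads
#'
#' At each CpG position of the reference: C is called methylated (1), T
#' unmethylated (0), any other base missing.
#'
#' @param sequences Character vector of reads oriented to the reference.
#' @param reference A `bisulfite_reference`.
#' @return Integer matrix reads x CpG sites (NA = missing), sites in the
#'   reference strand's 5'->3' order.
#' @export
call_cpgs <- function(sequences, reference) {
  cpg <- reference$cpg_positions
  m <- seq_matrix(sequences)[cpg, , drop = FALSE]
  calls <- matrix(NA_integer_, length(sequences), length(cpg))
  calls[t(m == "C")] <- 1L
  calls[t(m == "T")] <- 0L
  calls
}

#' Binomial coverage filter for region-level measurements
#'
#' A measurement (one library x amplicon mean methylation) is retained when
#' its read depth makes the estimate precise enough: the binomial standard
#' deviation `sqrt(p(1-p)/n)` of the region mean must give a coefficient of
#' variation below `cv_threshold`, or an absolute standard deviation not
#' above `sd_threshold` (the CV condition alone is too stringent for very
#' small methylation percentages). Zero reads is never retained.
#'
#' @param p_hat Region mean methylation fraction(s) in `[0,1]`.
#' @param n Read count(s).
#' @param cv_threshold CV bound (strict `<`), default 5%.
#' @param sd_threshold SD bound (inclusive `<=`), default 1%.
#' @return data.frame `sd`, `cv`, `retained`.
#' @export
coverage_filter <- function(p_hat, n, cv_threshold = 0.05,
                            sd_threshold = 0.01) {
  stopifnot(all(is.na(p_hat) | (p_hat >= 0 & p_hat <= 1)), all(n >= 0))
  sd_est <- sqrt(p_hat * (1 - p_hat) / pmax(n, 1))
  cv <- ifelse(p_hat > 0, sd_est / p_hat, Inf)
  retained <- !is.na(p_hat) & n > 0 &
    (cv < cv_threshold | sd_est <= sd_threshold)
  data.frame(sd = sd_est, cv = cv, retained = retained)
}

#' Call methylation from FASTQ to a methylation matrix
#'
#' Runs the four calling stages: demultiplex by barcode, assign reads to
#' amplicons with bisulfite-aware matching, discard reads below the minimal
#' conversion rate, call per-CpG states, then aggregate to site fractions
#' and region means with the coverage filter. Bottom-strand and reverse
#' reads are reoriented so all calls are reported in top-strand site order.
#'
#' @param reads data.frame `read_id`, `sequence`, or a FASTQ path.
#' @param panel An `amplicon_panel` with sequences.
#' @param sample_sheet data.frame with `library_id`, `barcode` (and any
#'   sample metadata columns, carried through).
#' @param min_conversion Minimal conversion rate; reads with a rate below
#'   it are discarded (threshold inclusive: rate >= min_conversion kept).
#' @param max_mismatch_frac Assignment threshold, see
#'   [assign_to_amplicon()].
#' @param adaptor_length See [demultiplex()].
#' @param filter_level Apply the coverage filter to region means
#'   (`"region"`, default) or additionally to per-site fractions
#'   (`"site"`).
#' @return A `methylation_matrix`: list with `site` (library x gene x site
#'   counts and fractions), `region` (region means, read counts, filter
#'   diagnostics, retained flag), `reads` (per-read call table), and `log`
#'   (read counts at every filtering step).
#' @export
call_methylation <- function(reads, panel, sample_sheet,
                             min_conversion = 0.97,
                             max_mismatch_frac = 0.1,
                             adaptor_length = 0,
                             filter_level = c("region", "site")) {
  filter_level <- match.arg(filter_level)
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  n_in <- nrow(reads)
  dm <- demultiplex(reads, sample_sheet, adaptor_length)
  asg <- assign_to_amplicon(dm$reads, panel, max_mismatch_frac)
  keep <- !is.na(asg$gene)
  rt <- cbind(dm$reads[keep, c("read_id", "library_id")],
              asg[keep, c("gene", "strand", "orientation", "mismatches")])
  seqs <- dm$reads$sequence[keep]
  # orient reads to their reference strand
  rev <- rt$orientation == "reverse"
  if (any(rev))
    seqs[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev])))
  refs <- list(top = lapply(setNames(panel$sequence, panel$gene),
                            bisulfite_convert, strand = "top"),
               bottom = lapply(setNames(panel$sequence, panel$gene),
                               bisulfite_convert, strand = "bottom"))
  rt$conversion_rate <- NA_real_
  rt$no_evidence <- FALSE
  rt$calls <- NA_character_
  ncpg <- setNames(panel$declared_n_cpg, panel$gene)
  call_mats <- list()
  grp <- paste(rt$gene, rt$strand)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    gene <- rt$gene[sel[1]]; strand <- rt$strand[sel[1]]
    ref <- refs[[strand]][[gene]]
    cr <- conversion_rate(seqs[sel], ref)
    rt$conversion_rate[sel] <- cr$conversion_rate
    rt$no_evidence[sel] <- cr$no_evidence
    calls <- call_cpgs(seqs[sel], ref)
    # bottom-strand site i pairs with top-strand site n+1-i
    if (strand == "bottom") calls <- calls[, rev(seq_len(ncol(calls))),
                                           drop = FALSE]
    call_mats[[g]] <- list(sel = sel, calls = calls)
  }
  for (g in names(call_mats)) {
    calls <- call_mats[[g]]$calls
    str <- matrix(".", nrow(calls), ncol(calls))
    str[!is.na(calls)] <- as.character(calls[!is.na(calls)])
    rt$calls[call_mats[[g]]$sel] <- apply(str, 1, paste, collapse = "")
  }
  # conversion filter: inclusive threshold; no-evidence reads retained+flagged
  pass <- rt$no_evidence |
    (!is.na(rt$conversion_rate) & rt$conversion_rate >= min_conversion)
  rt$pass_conversion <- pass

  site <- aggregate_calls(rt, call_mats, pass)
  region <- summarize_regions(site, panel, filter_level)
  meta_cols <- setdiff(names(sample_sheet), c("barcode"))
  site <- merge(sample_sheet[, meta_cols], site, by = "library_id",
                sort = FALSE)
  region$region <- merge(sample_sheet[, meta_cols], region$region,
                         by = "library_id", sort = FALSE)
  structure(list(site = site, region = region$region, reads = rt,
                 log = data.frame(
                   reads_in = n_in, unassigned_barcode = dm$n_unassigned,
                   unassigned_amplicon = sum(!keep),
                   failed_conversion = sum(!pass),
                   retained_reads = sum(pass),
                   measurements = nrow(region$region),
                   retained_measurements = sum(region$region$retained))),
            class = "methylation_matrix")
}

# site-level counts over retained reads
aggregate_calls <- function(rt, call_mats, pass) {
  chunks <- list()
  for (g in names(call_mats)) {
    sel <- call_mats[[g]]$sel
    keep <- pass[sel]
    if (!any(keep)) next
    calls <- call_mats[[g]]$calls[keep, , drop = FALSE]
    libs <- rt$library_id[sel[keep]]
    gene <- rt$gene[sel[1]]
    for (lib in unique(libs)) {
      rows <- libs == lib
      meth <- colSums(calls[rows, , drop = FALSE] == 1L, na.rm = TRUE)
      tot <- colSums(!is.na(calls[rows, , drop = FALSE]))
      k <- paste(gene, lib)
      if (!is.null(chunks[[k]])) {   # top and bottom strand of same gene
        chunks[[k]]$meth <- chunks[[k]]$meth + meth
        chunks[[k]]$total <- chunks[[k]]$total + tot
        chunks[[k]]$n_reads <- chunks[[k]]$n_reads + sum(rows)
        chunks[[k]]$fraction <- ifelse(chunks[[k]]$total > 0,
                                       chunks[[k]]$meth / chunks[[k]]$total,
                                       NA_real_)
      } else {
        chunks[[k]] <- data.frame(
          library_id = lib, gene = gene, site = seq_along(meth),
          meth = meth, total = tot,
          fraction = ifelse(tot > 0, meth / tot, NA_real_),
          n_reads = sum(rows), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(chunks))
    return(data.frame(library_id = character(0), gene = character(0),
                      site = integer(0), meth = integer(0),
                      total = integer(0), fraction = numeric(0),
                      n_reads = integer(0)))
  do.call(rbind, c(chunks, make.row.names = FALSE))
}

summarize_regions <- function(site, panel, filter_level) {
  if (nrow(site) == 0) {
    return(list(region = data.frame(
      library_id = character(0), gene = character(0),
      mean_methylation = numeric(0), n_reads = integer(0), sd = numeric(0),
      cv = numeric(0), retained = logical(0))))
  }
  key <- paste(site$library_id, site$gene)
  agg <- do.call(rbind, lapply(split(site, key), function(d) {
    usable <- d$total > 0
    data.frame(library_id = d$library_id[1], gene = d$gene[1],
               mean_methylation = if (any(usable))
                 mean(d$fraction[usable]) else NA_real_,
               n_reads = d$n_reads[1], stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  f <- coverage_filter(agg$mean_methylation, agg$n_reads)
  agg$sd <- f$sd; agg$cv <- f$cv; agg$retained <- f$retained
  if (filter_level == "site") {
    sf <- coverage_filter(site$fraction, site$total)
    site$site_retained <- sf$retained
  }
  list(region = agg)
}
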