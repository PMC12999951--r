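#' @importFrom stats cor sd var lm coef kruskal.test wilcox.test aov p.adjust
#'   median rbinom runif rgeom setNames pairwise.wilcox.test .lm.fit
#' @importFrom utils write.table read.delim
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Replicon constructor
#'
#' A replicon is a single DNA sequence with an identifier, topology and
#' completeness attribute. Sequences are stored upper-case over the alphabet
#' `{A,C,G,T,N}`; anything else is rejected with the offending position named.
#'
#' @param id character scalar identifier.
#' @param sequence character scalar DNA sequence (case-insensitive on input).
#' @param topology `"circular"` or `"linear"`.
#' @param completeness `"complete"`, `"draft"` or `"unknown"`.
#' @return An object of class `replicon` with fields `id`, `sequence`,
#'   `length`, `topology`, `completeness`.
#' @export
replicon <- function(id, sequence, topology = c("circular", "linear"),
                     completeness = c("unknown", "complete", "draft")) {
  topology <- match.arg(topology)
  completeness <- match.arg(completeness)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop("replicon '", id, "': empty sequence")
  bad <- gregexpr(sprintf("[^%s]", paste(VALID_BASES, collapse = "")),
                  sequence)[[1L]]
  if (bad[1L] != -1L)
    stop("replicon '", id, "': invalid character '",
         substr(sequence, bad[1L], bad[1L]), "' at position ", bad[1L])
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 topology = topology, completeness = completeness),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology, x$completeness))
  invisible(x)
}

#' Read replicons from FASTA or GenBank
#'
#' One `replicon` per record, in input order. Lower-case bases are folded to
#' upper case. GenBank records carry topology (LOCUS line) and completeness
#' (DEFINITION containing "complete"); FASTA records take `default_topology`.
#'
#' @param path input file.
#' @param format `"fasta"` or `"genbank"`.
#' @param default_topology topology assigned when the format does not state one.
#' @return list of `replicon` objects.
#' @export
read_replicons <- function(path, format = c("fasta", "genbank"),
                           default_topology = "circular") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "fasta") {
    # BStringSet admits arbitrary letters so the alphabet check below can
    # report the offending position itself
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no records in '", path, "'")
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i) {
      s <- as.character(set[[i]])
      if (nchar(s) == 0L) stop("empty record '", ids[i], "' in '", path, "'")
      replicon(ids[i], s, topology = default_topology)
    })
  } else {
    gb <- parse_genbank(path)
    lapply(gb, function(rec)
      replicon(rec$id, rec$sequence, topology = rec$topology,
               completeness = rec$completeness))
  }
}

#' CDS feature table constructor
#'
#' Zero-based half-open internal coordinates. `frame_offset` is the number of
#' bases to skip (reading 5'->3' on the coding strand) before the first
#' complete codon, i.e. the GFF3 `phase`.
#'
#' @param replicon_id,start,end,strand,frame_offset equal-length vectors;
#'   `start`/`end` 0-based half-open, `strand` in `{"+","-"}`,
#'   `frame_offset` in `{0,1,2}`.
#' @return a `data.frame` of class `feature_table`.
#' @export
feature_table <- function(replicon_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          frame_offset = integer()) {
  stopifnot(all(strand %in% c("+", "-")), all(frame_offset %in% 0:2),
            all(start >= 0L), all(end > start))
  ft <- data.frame(replicon_id = as.character(replicon_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   frame_offset = as.integer(frame_offset),
                   stringsAsFactors = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Read CDS features from GFF3 or GenBank
#'
#' Source coordinates (1-based inclusive) are converted to 0-based half-open.
#' GFF3 `phase` maps to `frame_offset` (missing phase treated as 0). Features
#' on unknown strand (`.`/`*`) are dropped with a message giving the count.
#' Features wrapping the circular origin in GenBank `join()` locations are
#' split into parts with the frame carried across the split.
#'
#' @param path input file.
#' @param format `"gff3"` or `"genbank"`.
#' @param feature_type feature type to keep (default `"CDS"`; set `"gene"` to
#'   count any gene feature).
#' @param seq_lengths optional named integer vector of replicon lengths used to
#'   validate feature bounds.
#' @param strict if `TRUE`, out-of-bounds features raise an error instead of a
#'   warning + drop.
#' @return a `feature_table`.
#' @export
read_features <- function(path, format = c("gff3", "genbank"),
                          feature_type = "CDS", seq_lengths = NULL,
                          strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    strands <- as.character(GenomicRanges::strand(gr))
    unknown <- strands == "*"
    if (any(unknown))
      message(sum(unknown), " feature(s) on unknown strand dropped")
    gr <- gr[!unknown]
    phase <- gr$phase
    if (is.null(phase)) phase <- rep(0L, length(gr))
    phase[is.na(phase)] <- 0L
    ft <- feature_table(
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      frame_offset = as.integer(phase))
  } else {
    recs <- parse_genbank(path, features_only = FALSE)
    rows <- do.call(rbind, lapply(recs, function(rec) rec$features))
    if (is.null(rows)) return(feature_table())
    rows <- rows[rows$type == feature_type, , drop = FALSE]
    ft <- feature_table(rows$replicon_id, rows$start, rows$end, rows$strand,
                        rows$frame_offset)
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[ft$replicon_id]
    oob <- !is.na(len) & ft$end > len
    if (any(oob)) {
      msg <- paste0(sum(oob), " feature(s) extend beyond replicon length")
      if (strict) stop(msg) else warning(msg, "; dropped")
      ft <- ft[!oob, , drop = FALSE]
      class(ft) <- c("feature_table", "data.frame")
    }
  }
  ft
}

#' Write a feature table to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to 1-based
#' inclusive; `frame_offset` is written to the phase column. Re-reading with
#' [read_features()] round-trips exactly.
#'
#' @param features a `feature_table`.
#' @param path output file.
#' @param feature_type GFF3 type column value.
#' @export
write_features_gff3 <- function(features, path, feature_type = "CDS") {
  lines <- c("##gff-version 3",
             sprintf("%s\trepliskew\t%s\t%d\t%d\t.\t%s\t%d\tID=cds%06d",
                     features$replicon_id, feature_type,
                     features$start + 1L, features$end, features$strand,
                     features$frame_offset, seq_len(nrow(features))))
  writeLines(lines, path)
  invisible(path)
}

#' Per-position codon / strand-coverage labels
#'
#' Builds the label map every downstream skew computation consumes:
#' `codon_label[p]` is 0 for non-coding positions and 1/2/3 for the codon
#' position of coding base `p` (codons read 5'->3' on the coding strand, so a
#' minus-strand CDS is labelled right-to-left); `strand_cover[p]` is the GSB
#' contribution: +1 if covered only by plus-strand CDS, -1 if only by
#' minus-strand CDS, 0 otherwise.
#'
#' When CDS overlap, the overlapped positions take their codon label from the
#' longer feature (ties: smaller start). Opposite-strand overlap additionally
#' forces `strand_cover` to 0.
#'
#' @param replicon a `replicon`.
#' @param features a `feature_table` for this replicon.
#' @return list of class `position_labels` with `replicon_id`, `codon_label`
#'   and `strand_cover` (integer vectors of replicon length).
#' @export
build_position_labels <- function(replicon, features) {
  n <- replicon$length
  if (nrow(features) > 0L) {
    if (!all(features$replicon_id == replicon$id))
      stop("feature table contains replicon ids other than '", replicon$id, "'")
    if (any(features$end > n))
      stop("feature out of bounds: end beyond replicon length ", n)
  }
  codon <- integer(n)
  plus_cov <- integer(n)
  minus_cov <- integer(n)
  if (nrow(features) > 0L) {
    # codon labels: apply in increasing priority so the highest-priority
    # (longest, then smallest start) feature writes last
    width <- features$end - features$start
    ord <- order(width, -features$start)   # lowest priority first
    for (i in ord) {
      s <- features$start[i]; e <- features$end[i]
      fo <- features$frame_offset[i]
      p <- (s + 1L):e                        # 1-based genomic positions
      lab <- integer(length(p))              # offset bases stay non-coding
      if (e - s - fo >= 3L) {
        if (features$strand[i] == "+") {
          inframe <- p > s + fo
          lab[inframe] <- 1L + ((p[inframe] - 1L - s - fo) %% 3L)
        } else {
          inframe <- p <= e - fo
          lab[inframe] <- 1L + ((e - 1L - fo - (p[inframe] - 1L)) %% 3L)
        }
      }
      codon[p] <- lab
    }
    for (i in seq_len(nrow(features))) {
      p <- (features$start[i] + 1L):features$end[i]
      if (features$strand[i] == "+") plus_cov[p] <- 1L else minus_cov[p] <- 1L
    }
  }
  structure(list(replicon_id = replicon$id, codon_label = codon,
                 strand_cover = plus_cov - minus_cov),
            class = "position_labels")
}

# ---- minimal GenBank flat-file reader -------------------------------------
# Covers the subset needed here: LOCUS (id, topology), DEFINITION
# (completeness), FEATURES CDS with complement()/join() locations and
# /codon_start, ORIGIN sequence block. join() parts whose coordinates wrap the
# circular origin arrive as separate parts and keep the reading frame across
# the split.
parse_genbank <- function(path, features_only = FALSE) {
  lines <- readLines(path)
  bounds <- grep("^LOCUS", lines)
  if (length(bounds) == 0L) stop("no LOCUS line in '", path, "'")
  ends <- c(bounds[-1L] - 1L, length(lines))
  lapply(seq_along(bounds), function(k) {
    rec <- lines[bounds[k]:ends[k]]
    locus <- strsplit(trimws(rec[1L]), "\\s+")[[1L]]
    id <- locus[2L]
    topology <- if (any(grepl("circular", rec[1L]))) "circular" else "linear"
    defn <- grep("^DEFINITION", rec, value = TRUE)
    completeness <- if (length(defn) && grepl("complete", defn[1L],
                                              ignore.case = TRUE))
      "complete" else "unknown"
    ori <- grep("^ORIGIN", rec)
    seqstr <- ""
    if (length(ori)) {
      body <- rec[(ori[1L] + 1L):length(rec)]
      body <- body[!grepl("^//", body)]
      seqstr <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    feats <- parse_genbank_features(rec, id)
    list(id = id, topology = topology, completeness = completeness,
         sequence = seqstr, features = feats)
  })
}

parse_genbank_features <- function(rec, id) {
  fstart <- grep("^FEATURES", rec)
  if (!length(fstart)) return(NULL)
  fend <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
  fend <- if (length(fend)) min(fend) - 1L else length(rec)
  block <- rec[(fstart + 1L):fend]
  key_idx <- grep("^ {5}\\S", block)
  if (!length(key_idx)) return(NULL)
  out <- list()
  for (j in seq_along(key_idx)) {
    i0 <- key_idx[j]
    i1 <- if (j < length(key_idx)) key_idx[j + 1L] - 1L else length(block)
    body <- block[i0:i1]
    key <- sub("^ {5}(\\S+).*", "\\1", body[1L])
    # location may continue over lines until the first qualifier
    qual <- grep("^ {21}/", body)
    loc_end <- if (length(qual)) qual[1L] - 1L else length(body)
    loc <- paste(trimws(c(sub("^ {5}\\S+\\s+", "", body[1L]),
                          body[seq_len(loc_end)[-1L]])), collapse = "")
    cs_line <- grep("/codon_start=", body, value = TRUE)
    codon_start <- if (length(cs_line))
      as.integer(sub(".*codon_start=\"?([0-9]+)\"?.*", "\\1", cs_line[1L])) else 1L
    parts <- parse_genbank_location(loc)
    if (is.null(parts)) next
    fo <- codon_start - 1L
    # distribute frame across ordered parts (5'->3' on the coding strand)
    ord <- if (parts$strand[1L] == "-") rev(seq_len(nrow(parts))) else
      seq_len(nrow(parts))
    offs <- integer(nrow(parts))
    carry <- fo
    for (i in ord) {
      offs[i] <- carry
      carry <- (3L - ((parts$end[i] - parts$start[i] - carry) %% 3L)) %% 3L
    }
    out[[length(out) + 1L]] <-
      data.frame(replicon_id = id, type = key, start = parts$start,
                 end = parts$end, strand = parts$strand, frame_offset = offs,
                 stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

parse_genbank_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1L]]
  m <- regmatches(parts, regexec("^[<>]?([0-9]+)\\.\\.[<>]?([0-9]+)$", parts))
  ok <- vapply(m, length, 1L) == 3L
  if (!any(ok)) return(NULL)
  s <- as.integer(vapply(m[ok], `[`, "", 2L)) - 1L
  e <- as.integer(vapply(m[ok], `[`, "", 3L))
  data.frame(start = s, end = e, strand = strand, stringsAsFactors = FALSE)
}

# integer base codes used by the skew counters: A=1 C=2 G=3 T=4 N=0
base_codes <- function(replicon) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[as.integer(charToRaw(replicon$sequence))]
}

#' Reverse complement of a replicon
#' @param replicon a `replicon`.
#' @return a `replicon` with the reverse-complemented sequence.
#' @export
reverse_complement <- function(replicon) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(replicon$sequence)))
  replicon(paste0(replicon$id, "_rc"), rc, topology = replicon$topology,
           completeness = replicon$completeness)
}
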