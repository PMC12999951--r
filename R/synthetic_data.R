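#' Default codon-position nucleotide weights
#'
#' Coding-strand nucleotide probabilities for the three codon positions,
#' reflecting genetic-code-level constraints: position 1 favours G (excess of
#' G-starting codons for abundant amino acids), position 2 favours T and A
#' (hydrophobic/hydrophilic encoding) with C above G, position 3 is uniform
#' (degenerate position, left to the mutational regime).
#'
#' @return list of three named numeric 4-vectors (`A`, `C`, `G`, `T`), each
#'   summing to 1.
#' @export
default_codon_weights <- function() {
  list(pos1 = c(A = 0.24, C = 0.20, G = 0.34, T = 0.22),
       pos2 = c(A = 0.30, C = 0.22, G = 0.16, T = 0.32),
       pos3 = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

#' Configuration for the synthetic replicon generator
#'
#' Defaults describe a generic prokaryotic chromosome: 1 Mb circle, a single
#' origin with balanced replichores, 85% coding density, 300-codon mean gene
#' length (geometric), 75% of genes co-oriented with their local leading
#' strand, leading-strand C-to-G conversion probability (`beta`) 0.08 applied
#' at full strength to intergenic and third-codon positions and attenuated to
#' 25% at codon positions 1-2 (selective constraint), intergenic GC content
#' 0.5.
#'
#' @param length replicon length in bases (>= 8 * 4096).
#' @param ori_position 0-based origin position.
#' @param leading_fraction true leading-strand fraction ("div") in (0, 1).
#' @param beta leading-strand C->G conversion probability in `[0, 1)`.
#' @param p_lead probability a gene is co-oriented with its local leading
#'   strand.
#' @param gene_density target fraction of coding bases in (0, 1).
#' @param mean_gene_length mean gene length in codons (geometric).
#' @param codon_weights list of three 4-vectors as in
#'   [default_codon_weights()].
#' @param intergenic_gc GC content of intergenic background in (0, 1).
#' @param attenuation multiplier on `beta` at codon positions 1 and 2.
#' @param seed integer RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(length = 1048576L, ori_position = 0L,
                             leading_fraction = 0.5, beta = 0.08,
                             p_lead = 0.75, gene_density = 0.85,
                             mean_gene_length = 300L,
                             codon_weights = default_codon_weights(),
                             intergenic_gc = 0.5, attenuation = 0.25,
                             seed = 1L) {
  length <- as.integer(length)
  stopifnot(length >= 8L * 4096L,
            ori_position >= 0L, ori_position < length,
            leading_fraction > 0, leading_fraction < 1,
            beta >= 0, beta < 1, p_lead >= 0, p_lead <= 1,
            gene_density > 0, gene_density < 1,
            mean_gene_length >= 1L, intergenic_gc > 0, intergenic_gc < 1,
            attenuation >= 0, attenuation <= 1)
  for (w in codon_weights) {
    if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("each codon weight vector must be 4 non-negative values summing to 1")
  }
  if (3L * mean_gene_length > length %/% 4L)
    stop("infeasible: mean gene length comparable to replicon length")
  structure(list(length = length, ori_position = as.integer(ori_position),
                 leading_fraction = leading_fraction, beta = beta,
                 p_lead = p_lead, gene_density = gene_density,
                 mean_gene_length = as.integer(mean_gene_length),
                 codon_weights = codon_weights,
                 intergenic_gc = intergenic_gc, attenuation = attenuation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate an annotated circular replicon
#'
#' Generates a replicon carrying the compositional structure the skew analysis
#' assumes, at its mutation/selection equilibrium (no forward simulation):
#'
#' 1. the circle is split at `ori_position` into a leading arc of
#'    `leading_fraction * length` bases (reference strand replicated as the
#'    leading strand) and a lagging arc (reference strand lagging);
#' 2. non-overlapping genes (length geometric in codons) are placed to the
#'    target coding density, each co-oriented with its local leading strand
#'    with probability `p_lead`;
#' 3. coding positions are drawn from the codon-position weights on the
#'    gene's coding strand and written as the corresponding reference-strand
#'    base; intergenic positions come from a background of GC content
#'    `intergenic_gc`;
#' 4. replication-driven mutational bias: wherever the reference strand is
#'    the leading strand, a reference C flips to G with probability `beta`;
#'    on the other arc a reference G flips to C — net G-enrichment of the
#'    leading strand everywhere. The flip probability is multiplied by
#'    `attenuation` at codon positions 1-2.
#'
#' Deterministic given the config (seed included).
#'
#' @param config a `synthetic_config`.
#' @return list with elements `replicon`, `features` (`feature_table`, all
#'   phase 0) and `truth` (list: `true_div`, `ori_bp`, `ter_bp` 1-based,
#'   `beta`, `p_lead`, `genes` data.frame with strand and replichore).
#' @export
simulate_replicon <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sim_id <- sprintf("synthetic_seed%d", config$seed)
  n <- config$length
  ori <- config$ori_position
  ter <- (ori + as.integer(round(config$leading_fraction * n))) %% n
  # TRUE where the reference (plus) strand is the leading strand
  pos0 <- 0:(n - 1L)
  on_lead_arc <- if (ori < ter) pos0 >= ori & pos0 < ter else
    pos0 >= ori | pos0 < ter

  # --- gene placement -------------------------------------------------------
  mean_gene_bp <- 3 * config$mean_gene_length
  gap_mean <- mean_gene_bp * (1 - config$gene_density) / config$gene_density
  n_est <- ceiling(n / (mean_gene_bp + gap_mean)) * 2L + 20L
  gene_codons <- 1L + rgeom(n_est, 1 / config$mean_gene_length)
  gaps <- if (gap_mean > 0) rgeom(n_est, 1 / (gap_mean + 1)) else
    integer(n_est)
  starts <- ends <- integer(0)
  cursor <- gaps[1L]
  i <- 1L
  while (i <= n_est) {
    glen <- 3L * gene_codons[i]
    if (cursor + glen > n) break
    starts <- c(starts, cursor); ends <- c(ends, cursor + glen)
    cursor <- cursor + glen + gaps[min(i + 1L, n_est)]
    i <- i + 1L
  }
  if (length(starts) == 0L) stop("infeasible: no gene fits the replicon")
  mid <- (starts + ends) %/% 2L
  gene_lead_plus <- on_lead_arc[mid + 1L]  # local leading strand is '+'
  co <- runif(length(starts)) < config$p_lead
  # a co-oriented gene sits on its local leading strand
  strand <- ifelse(co == gene_lead_plus, "+", "-")
  features <- feature_table(replicon_id = rep(sim_id, length(starts)),
                            start = starts, end = ends, strand = strand,
                            frame_offset = rep(0L, length(starts)))

  # --- composition ----------------------------------------------------------
  # base codes 1=A 2=C 3=G 4=T; labels via the same labeller the analysis uses
  codes <- integer(n)
  pgc <- config$intergenic_gc
  bg <- c((1 - pgc) / 2, pgc / 2, pgc / 2, (1 - pgc) / 2)
  stub <- structure(list(id = sim_id, sequence = "", length = n),
                    class = "replicon")
  labels <- build_position_labels(stub, features)
  lab <- labels$codon_label
  cover <- labels$strand_cover
  noncoding <- lab == 0L
  codes[noncoding] <- sample.int(4L, sum(noncoding), replace = TRUE,
                                 prob = bg)
  comp <- c(4L, 3L, 2L, 1L)
  for (k in 1:3) {
    w <- config$codon_weights[[k]]
    sel_p <- lab == k & cover == 1L
    sel_m <- lab == k & cover == -1L
    codes[sel_p] <- sample.int(4L, sum(sel_p), replace = TRUE, prob = w)
    codes[sel_m] <- comp[sample.int(4L, sum(sel_m), replace = TRUE,
                                    prob = w)]
  }

  # --- strand-specific mutational bias -------------------------------------
  beta_eff <- config$beta * ifelse(lab %in% c(1L, 2L), config$attenuation, 1)
  hit <- runif(n) < beta_eff
  to_g <- hit & on_lead_arc & codes == 2L
  to_c <- hit & !on_lead_arc & codes == 3L
  codes[to_g] <- 3L
  codes[to_c] <- 2L

  seq_chr <- paste(c("A", "C", "G", "T")[codes], collapse = "")
  rep_out <- replicon(sim_id, seq_chr, topology = "circular",
                      completeness = "complete")
  truth <- list(true_div = config$leading_fraction, ori_bp = ori + 1L,
                ter_bp = ter + 1L, beta = config$beta,
                p_lead = config$p_lead,
                genes = data.frame(start = starts, end = ends,
                                   strand = strand,
                                   leading_strand_is_plus = gene_lead_plus,
                                   co_oriented = co,
                                   stringsAsFactors = FALSE))
  list(replicon = rep_out, features = features, truth = truth)
}

#' Write a simulated replicon to FASTA + GFF3 + ground-truth JSON
#'
#' Emits `<prefix>.fasta`, `<prefix>.gff3` (CDS features, phase 0) and
#' `<prefix>.truth.json`; the FASTA/GFF3 pair is consumed unchanged by
#' [read_replicons()] / [read_features()].
#'
#' @param config a `synthetic_config`.
#' @param prefix output path prefix.
#' @return invisible named vector of the three file paths.
#' @export
simulate_to_files <- function(config, prefix) {
  sim <- simulate_replicon(config)
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  truth <- paste0(prefix, ".truth.json")
  writeLines(c(paste0(">", sim$replicon$id),
               substring(sim$replicon$sequence,
                         seq(1L, sim$replicon$length, 70L),
                         pmin(seq(1L, sim$replicon$length, 70L) + 69L,
                              sim$replicon$length))),
             fa)
  write_features_gff3(sim$features, gff)
  jsonlite::write_json(sim$truth[setdiff(names(sim$truth), "genes")], truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, truth = truth))
}
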