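#' Evaluate code under a temporary, fully specified RNG state
#'
#' Sets the generator kinds explicitly (Mersenne-Twister / Inversion /
#' Rejection) so results are stable across sessions, and restores the
#' caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

## Per-generator substream offsets: one global seed, independent streams, so
## adding a generator never perturbs existing fixtures.
.SUBSTREAM <- c(annotation = 11L, genes = 23L, hits = 37L, labels = 53L,
                orders = 71L)
.substream <- function(seed, which) (seed %% 1000000000L) + .SUBSTREAM[[which]]

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults that
#' emulate the study conditions the package targets: a repeat landscape
#' totalling roughly a quarter of the genome (the upper end reported for
#' nematode assemblies, with ~12% the lower, C. elegans-like bound),
#' LINEs as the most abundant TE class, tool suites containing two
#' deliberately correlated pairs (a machine-learning/consensus pair and a
#' low-complexity-masker pair) plus weaker independent tools, a species
#' ladder of nine non-focal genomes, three classifiers with distinct error
#' rates, and three-species gene orders with planted focal-lineage
#' transposon insertions.
#'
#' @param seed integer seed (mandatory); all generators derive independent
#'   substreams from it.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param class_density named vector, target fraction of the genome truly
#'   covered by each TE class (defaults sum to 0.24).
#' @param class_mean_length named vector of mean element lengths (bp).
#' @param superfamilies named list class -> candidate superfamily labels.
#' @param tools named list; each entry is a list with `sensitivity`,
#'   `fpr` (false-positive masked fraction of the genome), `jitter_sd`
#'   (boundary jitter, bp) and optional `latent` (tools sharing a latent id
#'   are generated from one shared latent mask).
#' @param pair_flip per-element membership flip probability applied to each
#'   partner of a latent pair (default 0.05).
#' @param density_gradient `"uniform"`, `"linear"` (density rising along the
#'   chromosome) or `"arms"` (density rising towards both ends).
#' @param gradient_strength relative density increase of the gradient.
#' @param n_contained_per_superfamily named vector: how many single-exon
#'   transcripts to plant fully inside elements of each superfamily.
#' @param n_half_coverage number of exons planted at exactly 50% coverage.
#' @param n_clear_genes number of genes planted free of any repeat.
#' @param n_multi_isoform number of two-isoform genes for merge tests.
#' @param exon_length_range min/max planted exon length (bp; even numbers).
#' @param n_genes_hits,n_species hit-table dimensions (genes, ladder size K).
#' @param age_class_props length-`K+1` proportions of age classes 0..K.
#' @param presence_prob probability of a hit at a species nearer than the
#'   gene's age-class-defining species.
#' @param overlap_fractions named list te_class -> length-`K+1` vector of the
#'   planted fraction of each age class overlapping that repeat class.
#' @param n_elements_labels number of classifier-evaluated elements.
#' @param flip_rates named per-method probability of mislabelling the TE
#'   class (class level).
#' @param label_class_props proportions of true DNA transposons vs
#'   retrotransposons among evaluated elements.
#' @param n_families genes per species in the synteny fixture.
#' @param n_insertions planted focal-specific insertions.
#' @param shuffle_rate fraction of positions undergoing local adjacent swaps.
#' @param insertion_family family token of the planted insertions (multi-copy
#'   by construction, hence never an anchor).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chrI = 1e6),
                       class_density = c(LINE = 0.07, Simple_repeat = 0.05,
                                         DNA = 0.05, LTR = 0.03,
                                         RC_Helitron = 0.02, Penelope = 0.02),
                       class_mean_length = c(LINE = 800, Simple_repeat = 150,
                                             DNA = 600, LTR = 1200,
                                             RC_Helitron = 500, Penelope = 700),
                       superfamilies = list(
                         LINE = c("CR1", "RTE", "L2"),
                         LTR = c("Gypsy", "Pao"),
                         DNA = c("TcMar-Tc1", "Sola-3", "TcMar-m44", "Zisupton"),
                         RC_Helitron = "Helitron",
                         Penelope = "Penelope"),
                       tools = list(
                         red = list(sensitivity = 0.90, fpr = 0.030,
                                    jitter_sd = 20, latent = "ml_pair"),
                         repeatmodeler2 = list(sensitivity = 0.90, fpr = 0.030,
                                               jitter_sd = 20, latent = "ml_pair"),
                         dustmasker = list(sensitivity = 0.80, fpr = 0.020,
                                           jitter_sd = 10, latent = "dust_pair"),
                         sdust = list(sensitivity = 0.80, fpr = 0.020,
                                      jitter_sd = 10, latent = "dust_pair"),
                         trf = list(sensitivity = 0.55, fpr = 0.050,
                                    jitter_sd = 40),
                         ltrharvest = list(sensitivity = 0.25, fpr = 0.010,
                                           jitter_sd = 30)),
                       pair_flip = 0.05,
                       density_gradient = c("uniform", "linear", "arms"),
                       gradient_strength = 3,
                       n_contained_per_superfamily = c(CR1 = 30, `Sola-3` = 24,
                                                       Gypsy = 21, RTE = 8,
                                                       `TcMar-Tc1` = 5),
                       n_half_coverage = 15,
                       n_clear_genes = 40,
                       n_multi_isoform = 10,
                       exon_length_range = c(200, 1200),
                       n_genes_hits = 5000,
                       n_species = 9,
                       age_class_props = c(0.30, 0.10, 0.08, 0.07, 0.06, 0.06,
                                           0.06, 0.06, 0.06, 0.15),
                       presence_prob = 0.9,
                       overlap_fractions = list(
                         Simple_repeat = c(0.06, 0.08, 0.09, 0.10, 0.11, 0.05,
                                           0.12, 0.14, 0.186, 0.173),
                         DNA = rep(0.05, 10),
                         LINE = rep(0.04, 10),
                         LTR = rep(0.02, 10)),
                       n_elements_labels = 2000,
                       flip_rates = c(repeatmodeler2 = 0.05, deepte = 0.15,
                                      rfsb = 0.25),
                       label_class_props = c(DNA_transposon = 0.5,
                                             Retrotransposon = 0.5),
                       n_families = 500,
                       n_insertions = 20,
                       shuffle_rate = 0.05,
                       insertion_family = "ZISUPTON") {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  density_gradient <- match.arg(density_gradient)
  chrom_lengths <- unlist(chrom_lengths)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  ## named-vector parameters may arrive as YAML mappings (lists)
  class_density <- unlist(class_density)
  class_mean_length <- unlist(class_mean_length)
  n_contained_per_superfamily <- unlist(n_contained_per_superfamily)
  age_class_props <- unlist(age_class_props)
  flip_rates <- unlist(flip_rates)
  label_class_props <- unlist(label_class_props)
  overlap_fractions <- lapply(overlap_fractions, unlist)
  if (sum(class_density) > 1)
    stop("total repeat density exceeds 1: infeasible for any chromosome length")
  stopifnot(all(class_density >= 0),
            all(names(class_density) %in% TE_CLASSES),
            abs(sum(age_class_props) - 1) < 1e-8,
            length(age_class_props) == n_species + 1,
            all(unlist(overlap_fractions) >= 0),
            all(unlist(overlap_fractions) <= 1),
            pair_flip >= 0, pair_flip <= 1, shuffle_rate >= 0,
            all(vapply(overlap_fractions, length, 1L) == n_species + 1))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## Draw element lengths averaging `mean_len` until their sum is exactly
## `target` bp (last element trimmed; minimum length 20).
.draw_lengths <- function(target, mean_len) {
  if (target < 20) return(integer(0))
  n_guess <- max(16, ceiling(target / mean_len * 1.6))
  lens <- integer(0)
  while (sum(lens) < target)
    lens <- c(lens, pmax(20L, as.integer(round(stats::rexp(n_guess, 1 / mean_len)))))
  cum <- cumsum(lens)
  k <- which(cum >= target)[1]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - target)
  lens[lens >= 20]
}

## Place elements of given lengths without mutual overlap on [0, L): uniform
## mode distributes the free space as uniform spacings (exact total length);
## gradient modes sample start points from a tilted density and drop
## collisions.
.place_elements <- function(lens, L, gradient = "uniform", strength = 3) {
  n <- length(lens)
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (sum(lens) > L) stop("class density infeasible for chromosome length")
  if (gradient == "uniform") {
    free <- L - sum(lens)
    cuts <- sort(stats::runif(n)) * free
    start <- floor(cuts + c(0, cumsum(lens[-n])))
    out <- data.frame(start = start, end = start + lens)
    attr(out, "kept") <- seq_len(n)
    return(out)
  } else {
    u <- stats::runif(n)
    t <- if (gradient == "linear") {
      s <- strength
      (-1 + sqrt(1 + 2 * s * u * (1 + s / 2))) / s
    } else {
      ## arms: accept-reject against w(t) = 1 + s*|2t - 1|
      s <- strength
      t <- numeric(0)
      while (length(t) < n) {
        cand <- stats::runif(2 * n)
        acc <- stats::runif(2 * n) < (1 + s * abs(2 * cand - 1)) / (1 + s)
        t <- c(t, cand[acc])
      }
      t[seq_len(n)]
    }
    start <- sort(floor(t * (L - max(lens))))
    keep <- rep(TRUE, n)
    last_end <- -1
    for (i in seq_len(n)) {
      if (start[i] <= last_end) keep[i] <- FALSE
      else last_end <- start[i] + lens[i]
    }
    out <- data.frame(start = start[keep], end = start[keep] + lens[keep])
    attr(out, "kept") <- which(keep)
    out
  }
}

#' Simulate a multi-tool repeat-annotation suite
#'
#' Plants a ground-truth repeat landscape (per-class densities, no same-class
#' overlap, optional chromosomal density gradient) and derives one mask per
#' configured tool: true elements retained with the tool's sensitivity,
#' boundaries jittered, plus false-positive elements at the stated rate.
#' Tools sharing a `latent` id are generated from one shared latent mask with
#' independent per-element membership flips (`pair_flip`), planting the
#' correlated-pair structure that window clustering should recover. Fully
#' reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return List: `index` (genome index), `truth` (annotation set,
#'   source "truth"), `tools` (named list of annotation sets), `registry`
#'   (planted per-class bp and densities, tool parameters, latent pairs).
#' @export
simulate_annotation_suite <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.substream(cfg$seed, "annotation"), {
    index <- genome_index(names(cfg$chrom_lengths), cfg$chrom_lengths)
    truth_parts <- list()
    planted_bp <- stats::setNames(numeric(length(cfg$class_density)),
                                  names(cfg$class_density))
    for (ch in index$chrom) {
      L <- index$length[index$chrom == ch]
      ## draw per-class lengths, then place the pooled elements jointly so no
      ## two true elements overlap and planted densities are realized exactly
      lens <- integer(0); cls_of <- character(0)
      for (cls in names(cfg$class_density)) {
        target <- round(cfg$class_density[[cls]] * L)
        l <- .draw_lengths(target, cfg$class_mean_length[[cls]])
        lens <- c(lens, l)
        cls_of <- c(cls_of, rep(cls, length(l)))
      }
      if (length(lens) == 0) next
      perm <- sample.int(length(lens))
      lens <- lens[perm]; cls_of <- cls_of[perm]
      pos <- .place_elements(lens, L, cfg$density_gradient,
                             cfg$gradient_strength)
      cls_of <- cls_of[attr(pos, "kept")]
      sf <- vapply(cls_of, function(cl) {
        fams <- cfg$superfamilies[[cl]]
        if (is.null(fams)) "" else sample(fams, 1)
      }, "")
      truth_parts[[ch]] <- data.frame(
        chrom = ch, start = pos$start, end = pos$end, te_class = cls_of,
        superfamily = unname(sf), source = "truth", stringsAsFactors = FALSE)
      add <- tapply(pos$end - pos$start, cls_of, sum)
      planted_bp[names(add)] <- planted_bp[names(add)] + add
    }
    truth <- do.call(rbind, truth_parts)
    truth <- truth[order(truth$chrom, truth$start, method = "radix"), ]
    rownames(truth) <- NULL
    validate_annotation(truth, index)
    n_el <- nrow(truth)
    G <- sum(index$length)
    ## latent membership per latent id
    latents <- unique(unlist(lapply(cfg$tools, `[[`, "latent")))
    latent_member <- lapply(stats::setNames(latents, latents), function(l) {
      sens <- cfg$tools[[which(vapply(cfg$tools, function(t)
        identical(t$latent, l), logical(1)))[1]]]$sensitivity
      stats::runif(n_el) < sens
    })
    tools <- list()
    for (tn in names(cfg$tools)) {
      tl <- cfg$tools[[tn]]
      member <- if (!is.null(tl$latent)) {
        flip <- stats::runif(n_el) < cfg$pair_flip
        xor(latent_member[[tl$latent]], flip)
      } else stats::runif(n_el) < tl$sensitivity
      el <- truth[member, , drop = FALSE]
      if (nrow(el) && tl$jitter_sd > 0) {
        len0 <- el$end - el$start
        el$start <- el$start + round(stats::rnorm(nrow(el), 0, tl$jitter_sd))
        el$end <- el$end + round(stats::rnorm(nrow(el), 0, tl$jitter_sd))
        lenmax <- index$length[match(el$chrom, index$chrom)]
        el$start <- pmax(0, el$start)
        el$end <- pmin(lenmax, el$end)
        bad <- el$start >= el$end
        if (any(bad)) {  # jitter collapsed the element; restore original span
          el$start[bad] <- pmax(0, el$end[bad] - len0[bad])
          el$end[bad] <- el$start[bad] + len0[bad]
        }
      }
      ## false positives: unplaced intervals at the configured masked rate
      fp_bp <- tl$fpr * G
      if (fp_bp >= 300) {
        n_fp <- max(1, round(fp_bp / 300))
        fp_chr <- sample(index$chrom, n_fp, replace = TRUE,
                         prob = index$length / G)
        fp_len <- pmax(30L, as.integer(round(stats::rexp(n_fp, 1 / 300))))
        fp_max <- index$length[match(fp_chr, index$chrom)] - fp_len
        keep <- fp_max > 0
        fp_start <- floor(stats::runif(sum(keep)) * fp_max[keep])
        fp <- data.frame(chrom = fp_chr[keep], start = fp_start,
                         end = fp_start + fp_len[keep],
                         te_class = "Unknown", superfamily = "",
                         source = tn, stringsAsFactors = FALSE)
        el <- rbind(el, fp)
      }
      if (nrow(el)) el$source <- tn
      el <- el[order(el$chrom, el$start, method = "radix"), , drop = FALSE]
      rownames(el) <- NULL
      validate_annotation(el, index)
      tools[[tn]] <- el
    }
    registry <- list(
      planted_bp = planted_bp,
      planted_density = planted_bp / G,
      total_density = sum(planted_bp) / G,
      tool_params = cfg$tools,
      latent_pairs = local({
        lid <- vapply(cfg$tools, function(t)
          if (is.null(t$latent)) NA_character_ else t$latent, "")
        split(names(cfg$tools)[!is.na(lid)], lid[!is.na(lid)])
      })
    )
    list(index = index, truth = truth, tools = tools, registry = registry)
  })
}

#' Simulate a gene fixture with known repeat-overlap outcomes
#'
#' Lays planted units along one synthetic chromosome with generous spacing:
#' single-exon transcripts fully inside a repeat element of a prescribed
#' superfamily, exons overlapping a repeat by exactly half their (even)
#' length, repeat-free genes, and two-isoform genes for isoform-merge tests.
#' The registry records the planted outcome of every unit, so the overlap
#' pipeline can be checked record-for-record.
#'
#' @param cfg a [sim_config()].
#' @return List: `index`, `genes` (gene-model data.frame), `repeats`
#'   (annotation set, source "truth"), `registry` (data.frame of planted
#'   units: gene/transcript ids, kind, class, superfamily, planted fraction).
#' @export
simulate_gene_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.substream(cfg$seed, "genes"), {
    fam2cls <- c(CR1 = "LINE", RTE = "LINE", L2 = "LINE",
                 Gypsy = "LTR", Pao = "LTR",
                 `TcMar-Tc1` = "DNA", `Sola-3` = "DNA", `TcMar-m44` = "DNA",
                 Zisupton = "DNA", Helitron = "RC_Helitron",
                 Penelope = "Penelope")
    units <- list()
    for (sf in names(cfg$n_contained_per_superfamily))
      units <- c(units, replicate(cfg$n_contained_per_superfamily[[sf]],
                                  list(kind = "contained", sf = sf,
                                       cls = fam2cls[[sf]]), simplify = FALSE))
    half_cls <- c("DNA", "LINE", "Simple_repeat")
    units <- c(units, lapply(seq_len(cfg$n_half_coverage), function(i)
      list(kind = "half", sf = "", cls = half_cls[(i %% 3) + 1])))
    units <- c(units, replicate(cfg$n_clear_genes,
                                list(kind = "clear", sf = "", cls = ""),
                                simplify = FALSE))
    units <- c(units, replicate(cfg$n_multi_isoform,
                                list(kind = "multi", sf = "", cls = ""),
                                simplify = FALSE))
    units <- units[sample.int(length(units))]
    chrom <- "chrS"
    pos <- 1000
    genes <- list(); reps <- list(); reg <- list()
    elen_rng <- cfg$exon_length_range
    draw_even <- function() 2 * sample(seq(elen_rng[1] / 2, elen_rng[2] / 2), 1)
    for (i in seq_along(units)) {
      u <- units[[i]]
      gid <- sprintf("gene%04d", i)
      tid <- paste0(gid, ".t1")
      elen <- draw_even()
      if (u$kind == "contained") {
        pad <- sample(20:100, 2)
        el <- c(pos, pos + pad[1] + elen + pad[2])
        ex <- c(pos + pad[1], pos + pad[1] + elen)
        sfam <- if (u$cls %in% .NO_SUPERFAMILY) "" else u$sf
        reps[[i]] <- data.frame(chrom = chrom, start = el[1], end = el[2],
                                te_class = u$cls, superfamily = sfam,
                                source = "truth", stringsAsFactors = FALSE)
        genes[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                                 chrom = chrom, start = ex[1], end = ex[2],
                                 strand = "+", stringsAsFactors = FALSE)
        reg[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                               kind = "contained", te_class = u$cls,
                               superfamily = sfam, planted_fraction = 1,
                               stringsAsFactors = FALSE)
        pos <- el[2]
      } else if (u$kind == "half") {
        ## element, then an exon whose left half lies inside it
        el <- c(pos, pos + elen)  # element of exon length
        ex <- c(pos + elen / 2, pos + elen / 2 + elen)
        sfam <- if (u$cls %in% .NO_SUPERFAMILY) "" else
          sample(cfg$superfamilies[[u$cls]], 1)
        reps[[i]] <- data.frame(chrom = chrom, start = el[1], end = el[2],
                                te_class = u$cls, superfamily = sfam,
                                source = "truth", stringsAsFactors = FALSE)
        genes[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                                 chrom = chrom, start = ex[1], end = ex[2],
                                 strand = "+", stringsAsFactors = FALSE)
        reg[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                               kind = "half", te_class = u$cls,
                               superfamily = sfam, planted_fraction = 0.5,
                               stringsAsFactors = FALSE)
        pos <- ex[2]
      } else if (u$kind == "clear") {
        ex <- c(pos, pos + elen)
        genes[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                                 chrom = chrom, start = ex[1], end = ex[2],
                                 strand = "+", stringsAsFactors = FALSE)
        reg[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                               kind = "clear", te_class = "",
                               superfamily = "", planted_fraction = 0,
                               stringsAsFactors = FALSE)
        pos <- ex[2]
      } else {  # multi-isoform gene: overlapping exons across two isoforms
        off <- elen / 2
        genes[[i]] <- data.frame(
          gene_id = gid,
          transcript_id = c(paste0(gid, ".t1"), paste0(gid, ".t2")),
          chrom = chrom, start = c(pos, pos + off),
          end = c(pos + elen, pos + off + elen),
          strand = "+", stringsAsFactors = FALSE)
        reg[[i]] <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                               kind = "multi", te_class = "",
                               superfamily = "", planted_fraction = 0,
                               stringsAsFactors = FALSE)
        pos <- pos + off + elen
      }
      pos <- pos + 2 * elen_rng[2] + sample(500:1500, 1)  # clearance between units
    }
    genes <- do.call(rbind, genes)
    reps <- do.call(rbind, reps)
    registry <- do.call(rbind, reg)
    rownames(genes) <- rownames(reps) <- rownames(registry) <- NULL
    index <- genome_index("chrS", pos + 1000)
    validate_gene_models(genes, index)
    validate_annotation(reps, index)
    list(index = index, genes = genes, repeats = reps, registry = registry)
  })
}

#' Simulate a gene x species homology hit table
#'
#' Draws each gene's age class from the configured proportions, then builds
#' its hit row: a guaranteed hit at the class-defining species, hits at
#' nearer species with probability `presence_prob` (so rows need not be
#' monotone), and none beyond. Also plants, per age class and repeat class,
#' an exact number of repeat-overlapping genes
#' (`round(fraction * class size)`), recorded in the registry.
#'
#' @param cfg a [sim_config()].
#' @return List: `hits` (data.frame, `gene_id` + one 0/1 column per species),
#'   `overlaps` (data.frame `gene_id`, `te_class`), `registry` (planted age
#'   classes and the realized per-class overlap fractions).
#' @export
simulate_hit_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.substream(cfg$seed, "hits"), {
    n <- cfg$n_genes_hits
    K <- cfg$n_species
    gid <- sprintf("g%05d", seq_len(n))
    age <- sample(0:K, n, replace = TRUE, prob = cfg$age_class_props)
    hits <- matrix(0L, n, K, dimnames = list(gid, paste0("sp", seq_len(K))))
    for (i in seq_len(n)) {
      if (age[i] == 0) next
      hits[i, age[i]] <- 1L
      if (age[i] > 1) {
        nearer <- seq_len(age[i] - 1)
        hits[i, nearer] <- as.integer(stats::runif(length(nearer)) < cfg$presence_prob)
      }
    }
    overlaps <- list()
    planted <- list()
    for (cls in names(cfg$overlap_fractions)) {
      fr <- cfg$overlap_fractions[[cls]]
      for (a in 0:K) {
        in_class <- which(age == a)
        k <- round(fr[a + 1] * length(in_class))
        if (k > 0) {
          sel <- sample(in_class, k)
          overlaps[[paste(cls, a)]] <- data.frame(
            gene_id = gid[sel], te_class = cls, stringsAsFactors = FALSE)
        }
        planted[[paste(cls, a)]] <- data.frame(
          te_class = cls, age_class = a, n_genes = length(in_class),
          n_overlapping = k,
          fraction = if (length(in_class)) k / length(in_class) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    overlaps <- do.call(rbind, overlaps)
    rownames(overlaps) <- NULL
    planted <- do.call(rbind, planted)
    rownames(planted) <- NULL
    list(hits = data.frame(gene_id = gid, hits, stringsAsFactors = FALSE,
                           check.names = FALSE),
         overlaps = overlaps,
         registry = list(age_class = data.frame(gene_id = gid, age_class = age,
                                                stringsAsFactors = FALSE),
                         planted_overlaps = planted))
  })
}

#' Simulate a three-classifier label table
#'
#' Assigns each element a true TE class (and an order within it), then lets
#' every configured method report it, flipping the class-level label with the
#' method's flip rate (the reported order is redrawn within the flipped
#' class).
#'
#' @param cfg a [sim_config()].
#' @return List: `labels` (long data.frame `element_id`, `method`,
#'   `order_label`), `truth` (named class-level vector), `registry` (flip
#'   rates, class proportions).
#' @export
simulate_labels <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.substream(cfg$seed, "labels"), {
    n <- cfg$n_elements_labels
    eid <- sprintf("el%05d", seq_len(n))
    cls <- sample(names(cfg$label_class_props), n, replace = TRUE,
                  prob = cfg$label_class_props)
    draw_order <- function(cl, m) {
      if (cl == "DNA_transposon")
        sample(c("DNA", "RC_Helitron"), m, replace = TRUE, prob = c(0.8, 0.2))
      else
        sample(c("LINE", "LTR", "Penelope"), m, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
    }
    ord <- character(n)
    for (cl in unique(cls)) ord[cls == cl] <- draw_order(cl, sum(cls == cl))
    rows <- list()
    other <- c(DNA_transposon = "Retrotransposon",
               Retrotransposon = "DNA_transposon")
    for (m in names(cfg$flip_rates)) {
      flip <- stats::runif(n) < cfg$flip_rates[[m]]
      rep_cls <- ifelse(flip, other[cls], cls)
      rep_ord <- ord
      for (cl in unique(rep_cls[flip]))
        rep_ord[flip & rep_cls == cl] <- draw_order(cl, sum(flip & rep_cls == cl))
      rows[[m]] <- data.frame(element_id = eid, method = m,
                              order_label = rep_ord, stringsAsFactors = FALSE)
    }
    labels <- do.call(rbind, rows)
    rownames(labels) <- NULL
    list(labels = labels,
         truth = stats::setNames(cls, eid),
         registry = list(flip_rates = cfg$flip_rates,
                         class_props = cfg$label_class_props))
  })
}

#' Simulate three-species gene orders with planted focal insertions
#'
#' Builds a shared ancestral order of single-copy families, derives each
#' species' order by local adjacent swaps at `shuffle_rate`, and inserts
#' `n_insertions` focal-lineage-specific genes of `insertion_family` at
#' well-separated positions in the focal order only. The registry records
#' each planted insertion's gene id and flanking families.
#'
#' @param cfg a [sim_config()].
#' @return List: `focal`, `out1`, `out2` (gene-order data.frames), `registry`
#'   (data.frame of planted insertions).
#' @export
simulate_gene_orders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.substream(cfg$seed, "orders"), {
    n <- cfg$n_families
    fams <- sprintf("F%04d", seq_len(n))
    shuffle <- function(f) {
      k <- round(cfg$shuffle_rate * length(f))
      if (k > 0) {
        at <- sample(seq_len(length(f) - 1), k)
        for (i in at) f[c(i, i + 1)] <- f[c(i + 1, i)]
      }
      f
    }
    make_order <- function(species, f) {
      gene_order(species, "S1", seq_along(f),
                 paste0(substr(species, 1, 3), sprintf("_%05d", seq_along(f))), f)
    }
    out1 <- make_order("outgroup1", shuffle(fams))
    out2 <- make_order("outgroup2", shuffle(fams))
    ff <- shuffle(fams)
    ## insertion slots at least 5 apart, away from the ends
    slots <- integer(0)
    while (length(slots) < cfg$n_insertions) {
      cand <- sort(sample(seq(5, length(ff) - 5), cfg$n_insertions * 4))
      cand <- cand[c(TRUE, diff(cand) >= 5)]
      slots <- cand
    }
    slots <- slots[seq_len(cfg$n_insertions)]
    reg <- data.frame(slot = slots,
                      left_family = ff[slots], right_family = ff[slots + 1],
                      stringsAsFactors = FALSE)
    ff2 <- character(0); ins_mark <- logical(0)
    prev <- 0
    for (s in slots) {
      ff2 <- c(ff2, ff[(prev + 1):s], cfg$insertion_family)
      ins_mark <- c(ins_mark, rep(FALSE, s - prev), TRUE)
      prev <- s
    }
    ff2 <- c(ff2, ff[(prev + 1):length(ff)])
    ins_mark <- c(ins_mark, rep(FALSE, length(ff) - prev))
    focal <- make_order("focal", ff2)
    reg$gene_id <- focal$gene_id[ins_mark]
    reg$family <- cfg$insertion_family
    list(focal = focal, out1 = out1, out2 = out2, registry = reg)
  })
}
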