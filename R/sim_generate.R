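# Truth generation: toy genome, true transcript structures with planted AS
# isoforms, planted annotation errors, per-sample true expression.

rand_bases <- function(n, at_fraction) {
  if (n <= 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at_fraction / 2, at_fraction / 2,
                  (1 - at_fraction) / 2, (1 - at_fraction) / 2))
}

draw_intron_lengths <- function(n, mean_len) {
  if (n == 0) return(integer(0))
  draw <- function(k) pmin(10000L, pmax(10L,
    10L + as.integer(round(rgamma(k, shape = 2,
                                  scale = (mean_len - 10) / 2)))))
  draw(n)
}

# coding sequence under the ciliate code: ATG ... TGA with no internal
# in-frame TGA (TAA/TAG are glutamine and may occur freely)
rand_cds <- function(n_bases, at_fraction) {
  stopifnot(n_bases %% 3 == 0, n_bases >= 9)
  b <- rand_bases(n_bases, at_fraction)
  b[1:3] <- c("A", "T", "G")
  b[(n_bases - 2):n_bases] <- c("T", "G", "A")
  starts <- seq.int(4L, n_bases - 5L, by = 3L)
  tga <- starts[b[starts] == "T" & b[starts + 1L] == "G" &
                  b[starts + 2L] == "A"]
  # TGA -> TCA keeps the A+T count unchanged and cannot create a new stop
  b[tga + 1L] <- "C"
  b
}

#' Generate a synthetic truth set
#'
#' Builds a toy A+T-rich genome, true transcript structures (UTRs, GT-AG
#' introns, ciliate-code CDS from ATG to TGA), planted alternative-splicing
#' isoforms, planted intergenic transcribed regions, a mispredicted
#' annotation (fused/split models, boundary shifts, missing introns) and
#' per-sample true expression.  All downstream observable evidence is
#' derived from this truth by [simulate_observables()] and
#' [simulate_microarray()].
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (named character vector),
#'   `annotation` (the mispredicted [annotation()] the pipeline refines) and
#'   `truth` (class `sr_truth`: true gene table, exon table, planted AS
#'   events, planted misannotations, expression matrix, and the true
#'   annotation including UTRs).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sr_sim_config"))
  with_seed(config$seed, generate_truth_impl(config))
}

generate_truth_impl <- function(cfg) {
  samples <- stage_samples()

  ## ---- structures ----------------------------------------------------
  n_novel <- round(cfg$novel_fraction * cfg$n_genes)
  n_short <- round(cfg$novel_short_fraction * n_novel)
  ents <- list()
  for (i in seq_len(cfg$n_genes)) {
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
    ex <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex,
                 replace = TRUE)
    rem <- sum(ex) %% 3L
    if (rem) ex[n_ex] <- ex[n_ex] + (3L - rem)
    ints <- draw_intron_lengths(n_ex - 1L, cfg$intron_mean)
    ents[[length(ents) + 1L]] <- list(
      id = sprintf("GENE%04d", i), novel = FALSE, short = FALSE,
      ex = ex, ints = ints,
      utr5 = min(as.integer(round(rexp(1, 1 / cfg$utr5_mean))), 290L),
      utr3 = min(as.integer(round(rexp(1, 1 / cfg$utr3_mean))), 290L)
    )
  }
  for (i in seq_len(n_novel + n_short)) {
    short <- i > n_novel
    if (short) {
      ex <- sample(100:250, 1L)
      ints <- integer(0)
    } else {
      total <- 300L + as.integer(round(rexp(1, 1 / 618)))
      n_ex <- sample(1:3, 1L)
      ex <- rep(total %/% n_ex, n_ex)
      ex[n_ex] <- ex[n_ex] + total %% n_ex
      ints <- draw_intron_lengths(n_ex - 1L, cfg$intron_mean)
    }
    ents[[length(ents) + 1L]] <- list(
      id = sprintf("NOVEL%04d", i), novel = TRUE, short = short,
      ex = ex, ints = ints, utr5 = 0L, utr3 = 0L
    )
  }

  ## ---- layout ---------------------------------------------------------
  ord <- sample(seq_along(ents))
  scaf_names <- sprintf("scf%d", seq_len(cfg$n_scaffolds))
  cur_scaf <- 1L
  pos <- 1L + cfg$intergenic_min
  for (k in ord) {
    len <- with(ents[[k]], utr5 + sum(ex) + sum(ints) + utr3)
    if (pos + len + cfg$intergenic_min > cfg$scaffold_length) {
      cur_scaf <- cur_scaf + 1L
      pos <- 1L + cfg$intergenic_min
      if (cur_scaf > cfg$n_scaffolds ||
          pos + len + cfg$intergenic_min > cfg$scaffold_length)
        stop("infeasible packing: genes do not fit the configured scaffolds; ",
             "increase scaffold_length or n_scaffolds")
    }
    ents[[k]]$scaffold <- scaf_names[cur_scaf]
    ents[[k]]$start <- pos
    ents[[k]]$end <- pos + len - 1L
    ents[[k]]$strand <- sample(c("+", "-"), 1L)
    pos <- pos + len + cfg$intergenic_min +
      as.integer(round(rexp(1, 1 / 300)))
  }

  ## ---- genomic block coordinates --------------------------------------
  for (k in seq_along(ents)) {
    g <- ents[[k]]
    # transcript-oriented segment lengths: utr5, e1, i1, ..., en, utr3
    n_ex <- length(g$ex)
    tx_ex <- g$ex
    tx_ex[1] <- tx_ex[1] + g$utr5
    tx_ex[n_ex] <- tx_ex[n_ex] + g$utr3
    seg_len <- integer(0)
    for (j in seq_len(n_ex)) {
      seg_len <- c(seg_len, tx_ex[j])
      if (j < n_ex) seg_len <- c(seg_len, g$ints[j])
    }
    seg_end <- cumsum(seg_len)
    seg_start <- seg_end - seg_len + 1L
    L <- sum(seg_len)
    t2g <- function(t) if (g$strand == "+") g$start + t - 1L
                       else g$end - t + 1L
    blocks <- data.frame(
      kind = rep(c("exon", "intron"), length.out = 2 * n_ex - 1L),
      t_start = seg_start, t_end = seg_end
    )
    gs <- pmin(t2g(blocks$t_start), t2g(blocks$t_end))
    ge <- pmax(t2g(blocks$t_start), t2g(blocks$t_end))
    blocks$g_start <- gs
    blocks$g_end <- ge
    g$blocks <- blocks
    ex_b <- blocks[blocks$kind == "exon", , drop = FALSE]
    int_b <- blocks[blocks$kind == "intron", , drop = FALSE]
    g$exons_g <- ex_b[order(ex_b$g_start), c("g_start", "g_end")]
    g$introns_g <- int_b[order(int_b$g_start), c("g_start", "g_end"),
                         drop = FALSE]
    if (g$novel) {
      g$cds_start <- NA_integer_; g$cds_end <- NA_integer_
    } else if (g$strand == "+") {
      g$cds_start <- g$start + g$utr5
      g$cds_end <- g$end - g$utr3
    } else {
      g$cds_start <- g$start + g$utr3
      g$cds_end <- g$end - g$utr5
    }
    ents[[k]] <- g
  }

  ## ---- roles: AS, misannotation, stage up-regulation ------------------
  coding_idx <- which(!vapply(ents, `[[`, FALSE, "novel"))
  assigned <- rep(FALSE, length(ents))
  as_events <- list()
  type_order <- c("ir", "alt5", "alt3", "cassette")
  groups <- unique(samples$group)
  for (k in coding_idx) {
    g <- ents[[k]]
    n_int <- length(g$ints)
    # transcript-order intron index -> genomic interval
    int_iv <- function(j) {
      b <- g$blocks[g$blocks$kind == "intron", , drop = FALSE]
      c(b$g_start[j], b$g_end[j])
    }
    elig <- c(
      ir = n_int >= 1,
      alt5 = n_int >= 1 && any(g$ints >= 40),
      alt3 = n_int >= 1 && any(g$ints >= 40),
      cassette = n_int >= 2 &&
        any(g$ints[-n_int] + g$ex[-c(1, length(g$ex))][seq_len(max(0, n_int - 1))] +
              g$ints[-1] <= 10000)
    )
    u <- runif(1)
    acc <- 0
    chosen <- NA_character_
    for (ty in type_order) {
      if (!elig[[ty]]) next
      acc <- acc + cfg$as_rates[[ty]]
      if (u < acc) { chosen <- ty; break }
    }
    if (is.na(chosen)) next
    assigned[k] <- TRUE
    grp <- if (runif(1) < cfg$as_stage_specific_fraction)
      sample(names(cfg$as_stage_probs), 1L, prob = cfg$as_stage_probs)
    else NA_character_
    if (chosen == "ir") {
      j <- sample.int(n_int, 1L)
      iv <- int_iv(j)
      ev <- list(gene = g$id, type = "ir", intron_tx = j,
                 intron_start = iv[1], intron_end = iv[2],
                 alt_start = NA, alt_end = NA,
                 exon_start = NA, exon_end = NA, group = grp)
    } else if (chosen %in% c("alt5", "alt3")) {
      j <- sample(which(g$ints >= 40), 1L)
      iv <- int_iv(j)
      len <- g$ints[j]
      d <- sample(6:min(60, len - 10L), 1L)
      # shift the donor (alt5) or acceptor (alt3) d bases into the intron
      shift_left <- (chosen == "alt5") == (g$strand == "+")
      alt <- if (shift_left) c(iv[1] + d, iv[2]) else c(iv[1], iv[2] - d)
      ev <- list(gene = g$id, type = chosen, intron_tx = j,
                 intron_start = iv[1], intron_end = iv[2],
                 alt_start = alt[1], alt_end = alt[2],
                 exon_start = NA, exon_end = NA, group = grp, d = d)
    } else {
      # cassette: skip internal (transcript-order) exon kx
      ok <- which(vapply(seq_len(n_int - 1L), function(j)
        g$ints[j] + g$ex[j + 1L] + g$ints[j + 1L] <= 10000, TRUE))
      j <- if (length(ok) == 1L) ok else sample(ok, 1L)
      iv1 <- int_iv(j); iv2 <- int_iv(j + 1L)
      skip <- c(min(iv1[1], iv2[1]), max(iv1[2], iv2[2]))
      exon <- c(min(iv1[2], iv2[2]) + 1L, max(iv1[1], iv2[1]) - 1L)
      ev <- list(gene = g$id, type = "cassette", intron_tx = j,
                 intron_start = iv1[1], intron_end = iv1[2],
                 intron2_start = iv2[1], intron2_end = iv2[2],
                 alt_start = skip[1], alt_end = skip[2],
                 exon_start = exon[1], exon_end = exon[2], group = grp)
    }
    ents[[k]]$as_event <- ev
    as_events[[length(as_events) + 1L]] <- ev
  }
  # misannotation: split / boundary / missing_intron on single genes
  mis <- list()
  for (k in coding_idx) {
    if (assigned[k]) next
    g <- ents[[k]]
    n_int <- length(g$ints)
    u <- runif(1)
    r <- cfg$misannotation_rates
    if (u < r[["split"]] && length(g$ex) >= 2) {
      assigned[k] <- TRUE
      ents[[k]]$mis <- "split"
    } else if (u < r[["split"]] + r[["boundary"]] && n_int >= 1 &&
               any(g$ints >= 13)) {
      assigned[k] <- TRUE
      ents[[k]]$mis <- "boundary"
    } else if (u < r[["split"]] + r[["boundary"]] + r[["missing_intron"]] &&
               n_int >= 1) {
      assigned[k] <- TRUE
      ents[[k]]$mis <- "missing_intron"
    }
  }
  # fusion: adjacent unassigned same-strand coding genes on one scaffold
  lay <- data.frame(k = coding_idx,
                    scaf = vapply(ents[coding_idx], `[[`, "", "scaffold"),
                    start = vapply(ents[coding_idx], `[[`, 0L, "start"),
                    strand = vapply(ents[coding_idx], `[[`, "", "strand"))
  lay <- lay[order(lay$scaf, lay$start), ]
  i <- 1L
  while (i < nrow(lay)) {
    a <- lay$k[i]; b <- lay$k[i + 1L]
    if (lay$scaf[i] == lay$scaf[i + 1L] &&
        lay$strand[i] == lay$strand[i + 1L] &&
        !assigned[a] && !assigned[b] &&
        runif(1) < cfg$misannotation_rates[["fuse"]]) {
      assigned[c(a, b)] <- TRUE
      ents[[a]]$mis <- "fuse_first"
      ents[[b]]$mis <- "fuse_second"
      ents[[a]]$fuse_with <- ents[[b]]$id
      i <- i + 2L
    } else i <- i + 1L
  }
  # stage-specific up-regulation on remaining genes
  for (k in coding_idx) {
    if (assigned[k]) next
    if (runif(1) < cfg$stage_up_fraction) {
      assigned[k] <- TRUE
      ents[[k]]$up_group <- sample(names(cfg$stage_up_probs), 1L,
                                   prob = cfg$stage_up_probs)
    }
  }

  ## ---- sequence -------------------------------------------------------
  genome <- lapply(scaf_names, function(s)
    rand_bases(cfg$scaffold_length, cfg$at_noncoding))
  names(genome) <- scaf_names
  for (k in seq_along(ents)) {
    g <- ents[[k]]
    n_ex <- length(g$ex)
    cds <- if (g$novel) rand_bases(sum(g$ex), cfg$at_noncoding)
           else rand_cds(sum(g$ex), cfg$at_coding)
    ex_seqs <- split(cds, rep(seq_len(n_ex), times = g$ex))
    int_seqs <- lapply(seq_len(max(0L, n_ex - 1L)), function(j) {
      s <- rand_bases(g$ints[j], cfg$at_noncoding)
      s[1:2] <- c("G", "T")
      s[(length(s) - 1L):length(s)] <- c("A", "G")
      s
    })
    ev <- g$as_event
    if (!is.null(ev) && ev$type %in% c("alt5", "alt3")) {
      j <- ev$intron_tx; d <- ev$d
      len <- g$ints[j]
      if (ev$type == "alt5") int_seqs[[j]][c(d + 1L, d + 2L)] <- c("G", "T")
      else int_seqs[[j]][c(len - d - 1L, len - d)] <- c("A", "G")
    }
    tx <- c(rand_bases(g$utr5, cfg$at_noncoding))
    for (j in seq_len(n_ex)) {
      tx <- c(tx, ex_seqs[[j]])
      if (j < n_ex) tx <- c(tx, int_seqs[[j]])
    }
    tx <- c(tx, rand_bases(g$utr3, cfg$at_noncoding))
    seg <- if (g$strand == "+") tx else rev(chartr("ACGT", "TGCA", tx))
    genome[[g$scaffold]][g$start:g$end] <- seg
  }
  genome <- vapply(genome, paste, "", collapse = "")

  ## ---- expression -----------------------------------------------------
  n_ent <- length(ents)
  base_e <- 10^rnorm(n_ent, 0, cfg$expression_log10_sd)
  E <- outer(base_e, unlist(cfg$stage_profiles))
  colnames(E) <- samples$sample
  rownames(E) <- vapply(ents, `[[`, "", "id")
  for (k in seq_along(ents)) {
    up <- ents[[k]]$up_group
    if (!is.null(up))
      E[k, samples$group == up] <- E[k, samples$group == up] * cfg$stage_up_fold
  }

  ## ---- truth tables ---------------------------------------------------
  ids <- rownames(E)
  genes <- data.frame(
    gene_id = ids,
    scaffold = vapply(ents, `[[`, "", "scaffold"),
    strand = vapply(ents, `[[`, "", "strand"),
    start = vapply(ents, `[[`, 0L, "start"),
    end = vapply(ents, `[[`, 0L, "end"),
    cds_start = vapply(ents, function(g) g$cds_start, 0L),
    cds_end = vapply(ents, function(g) g$cds_end, 0L),
    utr5_len = vapply(ents, `[[`, 0L, "utr5"),
    utr3_len = vapply(ents, `[[`, 0L, "utr3"),
    n_exons = vapply(ents, function(g) length(g$ex), 0L),
    is_novel = vapply(ents, `[[`, FALSE, "novel"),
    novel_short = vapply(ents, `[[`, FALSE, "short"),
    up_group = vapply(ents, function(g)
      if (is.null(g$up_group)) NA_character_ else g$up_group, ""),
    base_expr = base_e,
    stringsAsFactors = FALSE
  )
  exon_rows <- do.call(rbind, lapply(ents, function(g)
    data.frame(gene_id = g$id, start = g$exons_g$g_start,
               end = g$exons_g$g_end, stringsAsFactors = FALSE)))
  ev_df <- if (length(as_events)) do.call(rbind, lapply(as_events, function(e)
    data.frame(gene_id = e$gene, type = e$type,
               intron_start = e$intron_start, intron_end = e$intron_end,
               intron2_start = if (!is.null(e$intron2_start))
                 e$intron2_start else NA_integer_,
               intron2_end = if (!is.null(e$intron2_end))
                 e$intron2_end else NA_integer_,
               alt_start = e$alt_start, alt_end = e$alt_end,
               exon_start = e$exon_start, exon_end = e$exon_end,
               group = if (is.na(e$group)) NA_character_ else e$group,
               stringsAsFactors = FALSE)))
  else data.frame(gene_id = character(0), type = character(0),
                  intron_start = integer(0), intron_end = integer(0),
                  intron2_start = integer(0), intron2_end = integer(0),
                  alt_start = integer(0), alt_end = integer(0),
                  exon_start = integer(0), exon_end = integer(0),
                  group = character(0), stringsAsFactors = FALSE)
  mis_df <- do.call(rbind, c(list(data.frame(
    model_id = character(0), kind = character(0), gene_ids = character(0),
    stringsAsFactors = FALSE)),
    lapply(ents, function(g) {
      if (is.null(g$mis) || g$mis == "fuse_second") return(NULL)
      if (g$mis == "fuse_first")
        data.frame(model_id = g$id, kind = "fuse",
                   gene_ids = paste(g$id, g$fuse_with, sep = ","),
                   stringsAsFactors = FALSE)
      else data.frame(model_id = g$id, kind = g$mis, gene_ids = g$id,
                      stringsAsFactors = FALSE)
    })))
  seqlengths <- setNames(rep(cfg$scaffold_length, cfg$n_scaffolds),
                         scaf_names)
  truth_ann <- annotation(
    genes[, c("gene_id", "scaffold", "strand", "cds_start", "cds_end")],
    exon_rows, seqlengths, provenance = "simulated truth")
  predicted <- build_predicted_annotation(ents, seqlengths)
  truth <- structure(list(
    config = cfg, samples = samples,
    genes = genes, exons = exon_rows, as_events = ev_df,
    misannotation = mis_df, expression = E,
    annotation = truth_ann
  ), class = "sr_truth")
  list(genome = genome, annotation = predicted, truth = truth)
}

# The mispredicted "published" annotation: CDS-only exons (no UTRs), with
# planted fuse/split/boundary/missing-intron errors; novel regions absent.
build_predicted_annotation <- function(ents, seqlengths) {
  genes <- list(); exons <- list()
  add_model <- function(id, scaf, strand, ex, cds) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, scaffold = scaf, strand = strand,
      cds_start = cds[1], cds_end = cds[2], stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      gene_id = id, start = ex$g_start, end = ex$g_end,
      stringsAsFactors = FALSE)
  }
  cds_exons <- function(g) {
    e <- g$exons_g
    e$g_start <- pmax(e$g_start, g$cds_start)
    e$g_end <- pmin(e$g_end, g$cds_end)
    e[e$g_end >= e$g_start, , drop = FALSE]
  }
  skip <- character(0)
  for (g in ents) {
    if (g$novel || g$id %in% skip) next
    mis <- if (is.null(g$mis)) "none" else g$mis
    e <- cds_exons(g)
    n_ex <- nrow(e)
    if (mis == "none" || mis == "fuse_second") {
      if (mis == "none")
        add_model(g$id, g$scaffold, g$strand, e,
                  c(g$cds_start, g$cds_end))
      next
    }
    if (mis == "boundary") {
      j <- which(diff(e$g_start) > 0)  # introns exist between rows j, j+1
      lens <- e$g_start[-1] - e$g_end[-n_ex] - 1L
      j <- which(lens >= 13)[1]
      e$g_end[j] <- e$g_end[j] + 3L
      add_model(g$id, g$scaffold, g$strand, e, c(g$cds_start, g$cds_end))
    } else if (mis == "missing_intron") {
      j <- 1L
      e$g_end[j] <- e$g_end[j + 1L]
      e <- e[-(j + 1L), , drop = FALSE]
      add_model(g$id, g$scaffold, g$strand, e, c(g$cds_start, g$cds_end))
    } else if (mis == "split") {
      j <- max(1L, n_ex %/% 2L)
      add_model(paste0(g$id, "a"), g$scaffold, g$strand,
                e[seq_len(j), , drop = FALSE],
                c(e$g_start[1], e$g_end[j]))
      add_model(paste0(g$id, "b"), g$scaffold, g$strand,
                e[(j + 1L):n_ex, , drop = FALSE],
                c(e$g_start[j + 1L], e$g_end[n_ex]))
    } else if (mis == "fuse_first") {
      partner <- Filter(function(x) x$id == g$fuse_with, ents)[[1]]
      skip <- c(skip, partner$id)
      e2 <- cds_exons(partner)
      both <- rbind(e, e2)
      both <- both[order(both$g_start), , drop = FALSE]
      add_model(g$id, g$scaffold, g$strand, both,
                range(c(g$cds_start, g$cds_end,
                        partner$cds_start, partner$cds_end)))
    }
  }
  annotation(do.call(rbind, genes), do.call(rbind, exons), seqlengths,
             provenance = "simulated mispredicted release")
}
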