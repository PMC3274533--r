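# Independent oracles used to cross-check the implementation.

# Brute-force AS classifier over a gene's junction set: enumerates every
# junction pair and triple directly from the documented geometric
# definitions, with no shared code with enumerate_as_events().
oracle_as_events <- function(strand, model_introns, internal_exons, jdf,
                             cov, scaffold, min_support = 2,
                             min_depth = 10) {
  donor <- function(i) if (strand == "-") jdf$end[i] else jdf$start[i]
  accept <- function(i) if (strand == "-") jdf$start[i] else jdf$end[i]
  sup <- jdf$support
  n <- nrow(jdf)
  ev <- list()
  # cassette triples
  cass_pairs <- matrix(nrow = 0, ncol = 2)
  if (n >= 3) for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    if (length(unique(c(x, y, z))) < 3) next
    if (jdf$start[z] != jdf$start[x] || jdf$end[z] != jdf$end[y]) next
    if (jdf$end[x] + 2 > jdf$start[y]) next
    exon <- c(jdf$end[x] + 1, jdf$start[y] - 1)
    if (!any(internal_exons$start == exon[1] &
               internal_exons$end == exon[2])) next
    if (sup[x] < min_support || sup[y] < min_support ||
          sup[z] < min_support) next
    ev[[length(ev) + 1]] <- list(type = "cassette",
                                 key = paste("cassette", exon[1], exon[2]))
    cass_pairs <- rbind(cass_pairs, c(x, z), c(y, z))
  }
  in_cass <- function(a, b) {
    nrow(cass_pairs) > 0 &&
      any((cass_pairs[, 1] == a & cass_pairs[, 2] == b) |
            (cass_pairs[, 1] == b & cass_pairs[, 2] == a))
  }
  # alt5/alt3 pairs
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (in_cass(a, b)) next
    if (sup[a] < min_support || sup[b] < min_support) next
    ty <- if (accept(a) == accept(b) && donor(a) != donor(b)) "alt5"
          else if (donor(a) == donor(b) && accept(a) != accept(b)) "alt3"
          else NA
    if (!is.na(ty)) {
      ka <- c(jdf$start[a], jdf$end[a]); kb <- c(jdf$start[b], jdf$end[b])
      if (kb[1] < ka[1] || (kb[1] == ka[1] && kb[2] < ka[2])) {
        tmp <- ka; ka <- kb; kb <- tmp
      }
      ev[[length(ev) + 1]] <- list(type = ty,
                                   key = paste(ty, ka[1], ka[2], kb[1], kb[2]))
    }
  }
  # intron retention
  for (j in seq_len(nrow(model_introns))) {
    s <- model_introns$start[j]; e <- model_introns$end[j]
    jm <- which(jdf$start == s & jdf$end == e)
    sp <- if (length(jm)) sup[jm[1]] else 0
    if (sp >= min_support && all(cov[s:e] >= min_depth))
      ev[[length(ev) + 1]] <- list(type = "ir", key = paste("ir", s, e))
  }
  if (!length(ev)) return(character(0))
  sort(unique(vapply(ev, function(e) e$key, "")))
}

# canonical event keys for comparing enumerate_as_events output with the
# oracle (alt events keyed by the unordered junction pair)
event_keys <- function(events) {
  if (!nrow(events)) return(character(0))
  keys <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    keys[i] <- switch(e$type,
      cassette = paste("cassette", e$exon_start, e$exon_end),
      ir = paste("ir", e$intron_start, e$intron_end),
      {
        a <- c(e$intron_start, e$intron_end)
        b <- c(e$alt_start, e$alt_end)
        if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { t <- a; a <- b; b <- t }
        paste(e$type, a[1], a[2], b[1], b[2])
      })
  }
  sort(unique(keys))
}

# Random toy-gene sweep comparing enumerate_as_events() with the brute-force
# oracle: genes with <= 4 introns, <= 6 candidate junctions drawn from
# annotated introns, shifted splice sites and exon skips.
oracle_sweep <- function(n_cases, seed) {
  set.seed(seed)
  samples <- stage_samples()
  mismatches <- 0L
  n_events <- 0L
  for (case in seq_len(n_cases)) {
    n_int <- sample(1:4, 1)
    ex_len <- sample(30:80, n_int + 1, replace = TRUE)
    in_len <- sample(20:60, n_int, replace = TRUE)
    starts <- integer(0); ends <- integer(0); pos <- 1L
    for (j in seq_len(n_int + 1)) {
      starts <- c(starts, pos); ends <- c(ends, pos + ex_len[j] - 1L)
      pos <- pos + ex_len[j] + (if (j <= n_int) in_len[j] else 0L)
    }
    exons <- data.frame(start = starts, end = ends)
    introns <- data.frame(start = ends[-(n_int + 1)] + 1L,
                          end = starts[-1] - 1L)
    strand <- sample(c("+", "-"), 1)
    gene <- data.frame(gene_id = "g", scaffold = "s", strand = strand,
                       cds_start = min(starts), cds_end = max(ends),
                       stringsAsFactors = FALSE)
    cand <- introns
    for (j in seq_len(nrow(introns))) {
      d <- sample(3:10, 1)
      cand <- rbind(cand,
                    data.frame(start = introns$start[j] + d,
                               end = introns$end[j]),
                    data.frame(start = introns$start[j],
                               end = introns$end[j] - d))
    }
    if (n_int >= 2) for (j in seq_len(n_int - 1))
      cand <- rbind(cand, data.frame(start = introns$start[j],
                                     end = introns$end[j + 1]))
    cand <- unique(cand)
    pick <- sample(nrow(cand), min(nrow(cand), sample(2:6, 1)))
    jdf <- cand[pick, , drop = FALSE]
    jdf$support <- sample(0:5, nrow(jdf), replace = TRUE)
    len <- max(exons$end) + 10L
    depth <- sample(c(0, 9, 12), 1)
    flat <- function(s) coverage_track(list(s = rep(depth, len)), sample = s)
    cg <- list(growth = flat("growth"), starvation = flat("starvation"),
               conjugation = flat("conjugation"))
    jx_df <- data.frame(scaffold = "s", start = jdf$start, end = jdf$end,
                        strand = strand, min_anchor = 20L, donor = "GT",
                        acceptor = "AG", canonical = TRUE,
                        stringsAsFactors = FALSE)
    for (s in samples$sample) jx_df[[paste0("support.", s)]] <-
      ifelse(rep(s == "G_m", nrow(jx_df)), jdf$support, 0L)
    js <- junctions(jx_df)
    gi <- introns; gi$length <- gi$end - gi$start + 1L
    got <- suppressMessages(
      enumerate_as_events(gene, exons, gi, js, cg, samples))
    internal <- exons[-c(1, nrow(exons)), , drop = FALSE]
    jss <- as.data.frame(js)
    want <- oracle_as_events(strand, introns, internal,
                             data.frame(start = jss$start, end = jss$end,
                                        support = junction_support(js)),
                             rep(depth * 3, len), "s")
    if (!identical(event_keys(got), want)) mismatches <- mismatches + 1L
    n_events <- n_events + length(want)
  }
  list(mismatches = mismatches, n_events = n_events)
}
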