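# GFF3/GTF annotation I/O.  Parsing and coordinate conventions are delegated
# to rtracklayer; this layer detects the dialect, maps features onto the
# package's gene-model container and enforces its structural invariants.

detect_gff_dialect <- function(path) {
  ln <- readLines(path, n = 500L)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) stop("no feature lines in ", path)
  attrs <- vapply(strsplit(ln, "\t"), function(x) x[min(9L, length(x))], "")
  gtf <- grepl("^\\s*[A-Za-z_]+ \"", attrs)
  gff3 <- grepl("^[A-Za-z_]+=", attrs)
  if (any(gtf) && any(gff3)) stop("mixed GTF/GFF3 attribute dialects in ", path)
  if (any(gtf)) "gtf" else if (any(gff3)) "gff3"
  else stop("cannot detect annotation dialect of ", path)
}

#' Read a gene-model annotation from GFF3 or GTF
#'
#' The dialect is auto-detected from the attribute syntax of the first data
#' lines; mixed files are rejected.  Exons are attached to genes either
#' directly (Parent = gene) or through an mRNA/transcript layer.  Exons of a
#' model are sorted (with a warning if the file was unsorted); a CDS feature
#' set defines the CDS span; exons outside the scaffold bounds declared by
#' `##sequence-region` pragmas raise an error naming the feature.
#'
#' @param path GFF3 or GTF file.
#' @return An [annotation()] object.
#' @export
read_annotation <- function(path) {
  dialect <- detect_gff_dialect(path)
  gr <- rtracklayer::import(path, format = dialect)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (dialect == "gtf") {
    df$gene <- df$gene_id
  } else {
    parent <- vapply(df$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, "")
    # resolve exon/CDS Parent through an mRNA layer if one exists
    rna <- df$type %in% c("mRNA", "transcript")
    rna_map <- setNames(parent[rna], df$ID[rna])
    df$gene <- ifelse(parent %in% names(rna_map),
                      unname(rna_map[parent]), parent)
    isgene <- df$type == "gene"
    df$gene[isgene] <- df$ID[isgene]
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(ex)) stop("no exon features in ", path)
  gid <- unique(ex$gene)
  genes <- data.frame(
    gene_id = gid,
    scaffold = ex$seqnames[match(gid, ex$gene)],
    strand = ex$strand[match(gid, ex$gene)],
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (nrow(cds)) {
    cs <- tapply(cds$start, cds$gene, min)
    ce <- tapply(cds$end, cds$gene, max)
    m <- match(genes$gene_id, names(cs))
    genes$cds_start <- as.integer(cs[m])
    genes$cds_end <- as.integer(ce[m])
  }
  exons <- data.frame(gene_id = ex$gene, start = ex$start, end = ex$end,
                      stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(pragma)) {
    pf <- strsplit(pragma, "\\s+")
    sl <- setNames(vapply(pf, function(x) as.integer(x[4]), 0L),
                   vapply(pf, function(x) x[2], ""))
  } else if (all(is.na(sl))) {
    sl <- tapply(df$end, df$seqnames, max)
    sl <- setNames(as.integer(sl), names(sl))
  }
  annotation(genes, exons, seqlengths = sl,
             provenance = basename(path))
}

#' Write a gene-model annotation as GFF3
#'
#' Emits gene, exon and CDS features (plus five_prime_UTR/three_prime_UTR
#' features where the exon span extends beyond the CDS), with deterministic
#' ordering (scaffold, start, id) and `##sequence-region` pragmas so that
#' read/write round-trips preserve the data model.
#'
#' @param ann An [annotation()] object.
#' @param path Output file.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  span <- gene_spans(ann)
  m <- match(g$gene_id, span$gene_id)
  rows <- list()
  add <- function(scaf, start, end, type, strand, id = NA, parent = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqnames = scaf, start = start, end = end, type = type,
      strand = strand, ID = id, Parent = parent, stringsAsFactors = FALSE)
  }
  for (i in order(g$scaffold, span$start[m], g$gene_id)) {
    gid <- g$gene_id[i]
    add(g$scaffold[i], span$start[m[i]], span$end[m[i]], "gene",
        g$strand[i], id = gid)
    e <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(e)))
      add(g$scaffold[i], e$start[j], e$end[j], "exon", g$strand[i],
          parent = gid)
    if (!is.na(g$cds_start[i])) {
      add(g$scaffold[i], g$cds_start[i], g$cds_end[i], "CDS", g$strand[i],
          parent = gid)
      utr_l <- e[e$end < g$cds_start[i], , drop = FALSE]
      utr_r <- e[e$start > g$cds_end[i], , drop = FALSE]
      part_l <- e[e$start < g$cds_start[i] & e$end >= g$cds_start[i], ,
                  drop = FALSE]
      part_r <- e[e$end > g$cds_end[i] & e$start <= g$cds_end[i], ,
                  drop = FALSE]
      lefts <- rbind(utr_l[, c("start", "end")],
                     if (nrow(part_l))
                       data.frame(start = part_l$start,
                                  end = g$cds_start[i] - 1L))
      rights <- rbind(if (nrow(part_r))
                        data.frame(start = g$cds_end[i] + 1L,
                                   end = part_r$end),
                      utr_r[, c("start", "end")])
      ltype <- if (g$strand[i] == "+") "five_prime_UTR" else "three_prime_UTR"
      rtype <- if (g$strand[i] == "+") "three_prime_UTR" else "five_prime_UTR"
      if (!is.null(lefts)) for (j in seq_len(nrow(lefts)))
        if (lefts$end[j] >= lefts$start[j])
          add(g$scaffold[i], lefts$start[j], lefts$end[j], ltype,
              g$strand[i], parent = gid)
      if (!is.null(rights)) for (j in seq_len(nrow(rights)))
        if (rights$end[j] >= rights$start[j])
          add(g$scaffold[i], rights$start[j], rights$end[j], rtype,
              g$strand[i], parent = gid)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  sl <- ann$seqlengths
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  rtracklayer::export(gr, path, format = "gff3")
  # deterministic header: drop volatile pragmas, declare scaffold bounds
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "##source-version") & !startsWith(ln, "##date")]
  pragmas <- sprintf("##sequence-region %s 1 %d", names(sl), unname(sl))
  writeLines(c(ln[1], pragmas, ln[-1]), path)
  invisible(path)
}
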