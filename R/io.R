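# Readers and writers for the standard formats the pipeline exchanges.
# Internal coordinates are 0-based half-open (BED-native); GFF3 and VCF are
# converted from/to their 1-based conventions at the boundary.

#' Read an association SNP table from TSV
#'
#' Expects columns `id`, `chrom`, `pos` (0-based), `pvalue`.
#' @param path File path.
#' @export
read_signals_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "pvalue")
  if (!all(need %in% names(x))) {
    stop_invalid("signal TSV must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Write / read a genotype panel as VCF
#'
#' Dosages are encoded as unphased GT fields (0 -> 0/0, 1 -> 0/1, 2 -> 1/1);
#' positions convert between the internal 0-based and VCF's 1-based
#' convention.
#'
#' @param panel A genotype panel.
#' @param path File path (plain-text `.vcf`).
#' @export
write_vcf_panel <- function(panel, path) {
  vt <- panel$variants
  d <- panel$dosages
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vt)), function(i) {
    paste(c(vt$chrom[i], vt$pos[i] + 1L, vt$id[i],
            vt$ref[i] %||% "A", vt$alt[i] %||% "C", ".", "PASS", ".",
            "GT", gt[d[, i] + 1L]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf_panel
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  variants <- data.frame(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  dosages <- t(dos)
  colnames(dosages) <- variants$id
  structure(list(variants = variants, dosages = dosages, blocks = NULL),
            class = "genotype_panel")
}

#' Write / read risk regions as BED
#'
#' The region id goes in the BED name column; seed SNP ids are written to a
#' side TSV (`<path>.seeds.tsv`).
#' @param regions Region data frame.
#' @param path BED file path.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$region_id
  )
  rtracklayer::export(gr, path, format = "BED")
  seeds <- data.frame(
    region_id = rep(regions$region_id, lengths(regions$seed_snps)),
    seed_snp = unlist(regions$seed_snps)
  )
  utils::write.table(seeds, paste0(path, ".seeds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    region_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write / read gene models as GFF3
#'
#' Each gene is one `gene` feature (attribute `ID`) with `CDS` children;
#' coordinates convert between 0-based half-open and GFF3's 1-based closed
#' convention. The TSS is implied by the strand (5' end of the gene body).
#'
#' @param genes Gene-model data frame (with `coding` list-column).
#' @param path GFF3 file path.
#' @export
write_gff3_genes <- function(genes, path) {
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tpostgwas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
    cd <- g$coding[[1]]
    for (j in seq_len(nrow(cd))) {
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tpostgwas\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        g$chrom, cd[j, 1] + 1L, cd[j, 2], g$strand, g$gene_id, j, g$gene_id)
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' @rdname write_gff3_genes
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  gg <- gr[is_gene]
  cds <- gr[gr$type == "CDS"]
  parent <- vapply(cds$Parent, function(p) p[[1]], character(1))
  strand <- as.character(BiocGenerics::strand(gg))
  start0 <- GenomicRanges::start(gg) - 1L
  end0 <- GenomicRanges::end(gg)
  coding <- lapply(gg$ID, function(id) {
    sel <- parent == id
    cbind(GenomicRanges::start(cds)[sel] - 1L, GenomicRanges::end(cds)[sel])
  })
  data.frame(
    gene_id = gg$ID,
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "-", end0 - 1L, start0),
    coding = I(coding), stringsAsFactors = FALSE
  )
}

#' Write / read gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path GMT file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read a sequence as FASTA
#' @param sequence Named character vector (chromosome -> sequence).
#' @param path FASTA path.
#' @export
write_fasta <- function(sequence, path) {
  x <- Biostrings::DNAStringSet(sequence)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a PWM library in JASPAR-style PFM text
#'
#' Format: a `>motif_id` header followed by four lines
#' `A [ n1 n2 ... ]` (rows A, C, G, T of counts or probabilities).
#'
#' @param library List of [pwm()] objects.
#' @param path File path.
#' @export
write_jaspar <- function(library, path) {
  lines <- unlist(lapply(library, function(m) {
    c(paste0(">", m$motif_id),
      vapply(1:4, function(r) {
        paste0(DNA_BASES[r], " [ ",
               paste(formatC(m$matrix[r, ], format = "f", digits = 6),
                     collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jaspar
#' @param pseudocount Pseudocount attached to the parsed matrices.
#' @export
read_jaspar <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  lapply(seq_along(headers), function(i) {
    id <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]][1]
    block <- lines[headers[i] + 1:4]
    rows <- lapply(block, function(l) {
      nums <- sub("^[ACGT]\\s*\\[?\\s*", "", l)
      nums <- sub("\\s*\\]\\s*$", "", nums)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    pwm(id, do.call(rbind, rows), pseudocount = pseudocount)
  })
}

#' Write a numeric matrix as TSV with a header line
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(data.frame(id = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

# Write the principal outputs of a run plus a manifest of row counts and
# parameters. Deterministic stages rewrite byte-identically for the same
# study and config.
write_run <- function(run, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) {
    utils::write.table(x, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    nrow(x)
  }
  counts <- c(
    regions = {
      write_regions_bed(run$regions, p("regions.bed"))
      nrow(run$regions)
    },
    candidates = tsv(
      data.frame(gene_id = run$candidates$gene_id,
                 relation = run$candidates$relation,
                 n_regions = run$candidates$n_regions,
                 region_ids = vapply(run$candidates$region_ids, paste,
                                     character(1), collapse = ",")),
      "candidates.tsv"),
    scores = tsv(run$scores, "gene_scores.tsv"),
    risk_variants = tsv(
      data.frame(run$risk_variants[, c("variant_id", "chrom", "pos", "tier",
                                       "score", "region_id")],
                 linked_genes = vapply(run$risk_variants$linked_genes, paste,
                                       character(1), collapse = ",")),
      "risk_variants.tsv"),
    motif_deltas = if (!is.null(run$motif_deltas)) {
      tsv(run$motif_deltas, "motif_deltas.tsv")
    } else 0L,
    survival = tsv(run$survival, "survival_screen.tsv"),
    celltype = if (!is.null(run$celltype_enrichment)) {
      tsv(run$celltype_enrichment, "celltype_enrichment.tsv")
    } else 0L
  )
  manifest <- data.frame(
    key = c("seed", "r2_min", "max_dist", "gap_max", "flank", "alpha",
            "precision_target", "n_perm", "n_boot",
            paste0("rows_", names(counts))),
    value = c(run$config$seed, run$config$r2_min, run$config$max_dist,
              run$config$gap_max, run$config$flank, run$config$alpha,
              run$config$precision_target, run$config$n_perm,
              run$config$n_boot, unname(counts))
  )
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_dir)
}
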