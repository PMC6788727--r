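#' Write genotypes as a GT-only VCF
#'
#' Minimal VCF 4.2 with one contig per chromosome, `INFO/GENE` carrying
#' the gene symbol, and unphased GT calls (`./.` for missing). Alleles
#' are placeholder A (major) / G (minor); the pipeline consumes only the
#' additive allele count.
#'
#' @param g a `genotype_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=szhc",
           sprintf("##contig=<ID=%s>", unique(g$snp_meta$chrom)),
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$subject_ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(g$calls)), function(s) {
    calls <- g$calls[, s]
    cells <- ifelse(is.na(calls), "./.", gt[calls + 1L])
    paste(c(g$snp_meta$chrom[s], g$snp_meta$pos[s], g$snp_meta$id[s],
            "A", "G", ".", "PASS",
            paste0("GENE=", g$snp_meta$gene[s]), "GT", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write/read genotypes as a PLINK-style .raw TSV
#'
#' Columns: subject then one column per SNP (additive 0/1/2, NA missing),
#' with a companion `<path>.snpmeta.tsv` carrying the SNP annotation.
#'
#' @param g a `genotype_matrix`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_plink_raw <- function(g, path) {
  df <- data.frame(subject = g$subject_ids, g$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$snp_meta, paste0(path, ".snpmeta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plink_raw
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(paste0(path, ".snpmeta.tsv"),
                            stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- df$subject
  genotype_matrix(calls, meta, df$subject)
}

#' Write a GMV image set as NIfTI volumes plus a subject manifest
#'
#' One `<subject>.nii.gz` per subject under `dir`, with a
#' `manifest.tsv` (subject, file) alongside.
#'
#' @param gmv a `gmv_image_set`
#' @param dir output directory (created if needed)
#' @return manifest path, invisibly
#' @export
write_gmv_nifti <- function(gmv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(gmv$data))
  for (i in seq_len(nrow(gmv$data))) {
    f <- file.path(dir, paste0(gmv$subject_ids[i], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(gmv_volume(gmv, i),
                                       pixdim = rep(gmv$voxel_size_mm, 3)), f)
    files[i] <- basename(f)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(subject = gmv$subject_ids, file = files,
               voxel_size_mm = gmv$voxel_size_mm),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a GMV image set from a subject manifest
#' @param manifest path to `manifest.tsv` written by [write_gmv_nifti()]
#' @return a `gmv_image_set`
#' @export
read_gmv_nifti <- function(manifest) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  vols <- lapply(tab$file, function(f)
    as.array(RNifti::readNifti(file.path(dir, f))))
  dimg <- dim(vols[[1]])
  data <- do.call(rbind, lapply(vols, as.vector))
  rownames(data) <- tab$subject
  gmv_image_set(data, dimg, tab$voxel_size_mm[1], tab$subject)
}

#' Write an expression set as expression + sample-metadata TSVs
#' @param expr an `expression_set`
#' @param expr_path genes x samples TSV (gene id in first column)
#' @param meta_path sample metadata TSV
#' @return `expr_path`, invisibly
#' @export
write_expression_tsv <- function(expr, expr_path, meta_path) {
  utils::write.table(
    data.frame(gene = rownames(expr$matrix), expr$matrix,
               check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(expr_path, meta_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  expression_set(m, meta)
}

#' Write ground truth as JSON plus NIfTI truth masks
#'
#' @param truth a `ground_truth`
#' @param dir output directory
#' @param voxel_size_mm voxel size recorded in the mask headers
#' @return path of the JSON file, invisibly
#' @export
write_ground_truth <- function(truth, dir, voxel_size_mm = 1.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(truth$true_cluster_masks)) {
    m <- truth$true_cluster_masks[[i]]
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(m), dim = dim(m)),
                      pixdim = rep(voxel_size_mm, 3)),
      file.path(dir, sprintf("truth_mask_%02d.nii.gz", i)))
  }
  js <- list(causal_snp_ids = truth$causal_snp_ids,
             causal_gene_ids = truth$causal_gene_ids,
             true_group_labels = truth$true_group_labels,
             planted_modules = truth$planted_modules,
             n_masks = length(truth$true_cluster_masks))
  path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
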