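# Plain-text fixture output for simulated cohorts (VCF subset, segment,
# counts, annotation and ground-truth tables) and the matching readers.
# Round-tripping a cohort through these files reproduces the in-memory
# values exactly.

#' Write cohort (and panel) fixtures to a directory
#'
#' Writes one VCF (v4.2 subset: CHROM, POS, REF, ALT, per-sample AD and DP,
#' channel in INFO) per patient, one segment TSV per biopsy, expression
#' counts/annotation/sample TSVs, ground-truth TSVs, and panel alt/depth
#' TSVs when a panel is supplied.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param panel optional `panel_counts` from [simulate_panel()].
#' @return named character vector of written file paths.
#' @export
write_fixtures <- function(cohort, dir, panel = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  paths <- character(0)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- path
    path
  }
  patients <- unique(cohort$calls$samples$patient)
  for (pid in patients) {
    v <- cohort$calls$variants[cohort$calls$variants$patient == pid, ,
                               drop = FALSE]
    alt <- cohort$calls$alt[[pid]]
    dep <- cohort$calls$depth[[pid]]
    path <- file.path(dir, paste0(pid, ".vcf"))
    con <- file(path, "w")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=CH,Number=1,Type=String,Description=\"Trinucleotide channel\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depth\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", colnames(alt)), collapse = "\t")), con)
    if (nrow(v)) {
      gt <- vapply(seq_len(ncol(alt)), function(s)
        sprintf("%d,%d:%d", dep[v$mut_id, s] - alt[v$mut_id, s],
                alt[v$mut_id, s], dep[v$mut_id, s]),
        character(nrow(v)))
      gt <- matrix(gt, nrow = nrow(v))
      lines <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                     v$mut_id, v$ref, v$alt, ".", "PASS",
                     paste0("CH=", v$channel), "AD:DP",
                     apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
      writeLines(lines, con)
    }
    close(con)
    paths[[basename(path)]] <- path
  }
  for (s in unique(cohort$segments$sample)) {
    tsv(cohort$segments[cohort$segments$sample == s, , drop = FALSE],
        paste0(s, "_segments.tsv"))
  }
  ex <- cohort$expression
  tsv(data.frame(gene = rownames(ex$counts), ex$counts, check.names = FALSE),
      "counts.tsv")
  tsv(ex$genes, "annotation.tsv")
  tsv(ex$samples, "rna_samples.tsv")
  tsv(cohort$calls$samples, "dna_samples.tsv")
  tsv(cohort$truth$mutations, "truth_mutations.tsv")
  tsv(cohort$truth$tree, "truth_tree.tsv")
  tsv(cohort$truth$ccf, "truth_ccf.tsv")
  if (!is.null(panel)) {
    tsv(data.frame(site = rownames(panel$alt), panel$alt,
                   check.names = FALSE), "panel_alt.tsv")
    tsv(data.frame(site = rownames(panel$depth), panel$depth,
                   check.names = FALSE), "panel_depth.tsv")
  }
  unlist(paths)
}

#' Read a VCF-subset call file written by [write_fixtures()]
#'
#' Minimal parser for the package's VCF subset: per-sample AD (ref,alt) and
#' DP fields and the trinucleotide channel from INFO/CH.
#'
#' @param path VCF file path.
#' @return list with `variants` (data.frame `mut_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `channel`) and matrices `alt` and `depth`.
#' @export
read_calls_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("no #CHROM header in ", path)
  cols <- strsplit(hdr, "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    empty <- matrix(0L, 0L, length(samples),
                    dimnames = list(NULL, samples))
    return(list(variants = data.frame(mut_id = character(0),
                                      chrom = character(0), pos = numeric(0),
                                      ref = character(0), alt = character(0),
                                      channel = character(0)),
                alt = empty, depth = empty))
  }
  f <- strsplit(body, "\t")
  getf <- function(i) vapply(f, `[`, character(1), i)
  variants <- data.frame(mut_id = getf(3L), chrom = getf(1L),
                         pos = as.numeric(getf(2L)), ref = getf(4L),
                         alt = getf(5L),
                         channel = sub("^CH=", "", getf(8L)))
  ad <- lapply(seq_along(samples) + 9L, function(i) {
    parts <- strsplit(getf(i), "[:,]")
    list(alt = vapply(parts, function(x) as.integer(x[2L]), integer(1)),
         depth = vapply(parts, function(x) as.integer(x[3L]), integer(1)))
  })
  alt <- do.call(cbind, lapply(ad, `[[`, "alt"))
  depth <- do.call(cbind, lapply(ad, `[[`, "depth"))
  dimnames(alt) <- dimnames(depth) <- list(variants$mut_id, samples)
  list(variants = variants, alt = alt, depth = depth)
}

#' Read a segment table TSV
#'
#' @param path TSV with columns `sample`, `chrom`, `start`, `end`, `major`,
#'   `minor`, `frac` (1-based inclusive coordinates).
#' @return data.frame.
#' @export
read_segment_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "major", "minor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read expression study fixtures
#'
#' @param counts_path,annotation_path,samples_path TSV paths as written by
#'   [write_fixtures()].
#' @return an [expression_study()].
#' @export
read_expression_tables <- function(counts_path, annotation_path,
                                   samples_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE)
  genes <- utils::read.delim(annotation_path,
                             colClasses = c(chrom = "character"))
  genes$exclusion_set[is.na(genes$exclusion_set)] <- ""
  samples <- utils::read.delim(samples_path)
  m <- as.matrix(cts[, -1L, drop = FALSE])
  rownames(m) <- cts[[1L]]
  storage.mode(m) <- "integer"
  expression_study(m, genes, samples)
}

#' Read panel counts from fixture TSVs
#'
#' @param alt_path,depth_path TSV paths as written by [write_fixtures()].
#' @return a `panel_counts` object.
#' @export
read_panel_tables <- function(alt_path, depth_path) {
  rd <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
  }
  structure(list(alt = rd(alt_path), depth = rd(depth_path),
                 error_rate = NA_real_, overdispersion = NA_real_),
            class = "panel_counts")
}
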