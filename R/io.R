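# Fixture-bundle I/O: plain tab-delimited files with a checksum manifest
# so a simulated multi-omics study can be written to disk, shared, and
# re-loaded bit-exactly.

fmt_num <- function(x) {
  # 17 significant digits guarantees double round-trip through text
  ifelse(is.na(x), ".", formatC(x, digits = 17, format = "g"))
}

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else ifelse(is.na(col), ".", as.character(col))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, numeric_cols = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in intersect(numeric_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  df
}

matrix_to_df <- function(m, id_col) {
  cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                        id_col),
        as.data.frame(m))
}

df_to_matrix <- function(df, id_col) {
  m <- as.matrix(df[setdiff(names(df), id_col)])
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  rownames(m) <- df[[id_col]]
  m
}

#' Write a synthetic study to a directory of TSV files with a manifest
#'
#' Emits one expression TSV per cohort, beta and CpG-map TSVs for both
#' promoters, sample annotation, the survival table, the planted truth,
#' and `manifest.txt` listing the MD5 checksum of every file. All files
#' are tab-delimited with a header row; missing values are written as
#' `"."`; CpG positions are 0-based half-open.
#'
#' @param sim list with any of `expression` (result of
#'   [generate_expression_cohorts()]), `methylation` (result of
#'   [generate_methylation()]), `survival` (a `survival_table`).
#' @param dir output directory (created if absent).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the manifest as a named character vector.
#' @export
write_fixture_bundle <- function(sim, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory exists and is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    write_tsv(df, file.path(dir, name))
    files <<- c(files, name)
  }

  truth <- NULL
  if (!is.null(sim$expression)) {
    truth <- sim$expression$truth
    ann <- list()
    for (co in sim$expression$collection$cohorts) {
      put(matrix_to_df(co$expr, "gene_id"),
          sprintf("expr_%s.tsv", co$name))
      ann[[co$name]] <- data.frame(sample_id = colnames(co$expr),
                                   cohort = co$name, histology = co$histology,
                                   group = co$groups, stringsAsFactors = FALSE)
    }
    put(do.call(rbind, c(ann, make.row.names = FALSE)),
        "annotation_expression.tsv")
  }
  if (!is.null(sim$methylation)) {
    m <- sim$methylation
    truth <- truth %||% m$truth
    put(as.data.frame(m$map), "cpg_map.tsv")
    put(matrix_to_df(m$beta, "probe_id"), "beta.tsv")
    put(as.data.frame(m$second$map), "cpg_map_second.tsv")
    put(matrix_to_df(m$second$beta, "probe_id"), "beta_second.tsv")
    put(data.frame(sample_id = colnames(m$beta), group = m$groups,
                   seed_expression = m$seed_expression,
                   stringsAsFactors = FALSE),
        "annotation_methylation.tsv")
  }
  if (!is.null(sim$survival)) put(as.data.frame(sim$survival), "survival.tsv")
  if (!is.null(truth)) {
    kv <- c(seed_gene = truth$seed_gene,
            planted_gene_ids = paste(truth$planted_gene_ids, collapse = ","),
            planted_region_start = truth$planted_region_bounds[["start"]],
            planted_region_end = truth$planted_region_bounds[["end"]],
            true_coupling = fmt_num(truth$true_coupling),
            true_log_hr = fmt_num(truth$true_log_hr),
            rng_seed = truth$rng_seed)
    writeLines(paste0(names(kv), "=", kv), file.path(dir, "truth.txt"))
    files <- c(files, "truth.txt")
  }

  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  writeLines(paste0(files, "=", sums), file.path(dir, "manifest.txt"))
  invisible(sums)
}

#' Read back a fixture bundle, verifying checksums
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return list with `expression` (cohort_collection), `methylation`
#'   (map/beta/groups/second/seed_expression), `survival` and `truth`,
#'   each present only if the bundle contains it.
#' @export
read_fixture_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.txt")
  if (!file.exists(mpath)) stop("no manifest.txt in ", dir)
  man <- strsplit(readLines(mpath), "=", fixed = TRUE)
  files <- vapply(man, `[`, "", 1L)
  expected <- vapply(man, `[`, "", 2L)
  actual <- unname(tools::md5sum(file.path(dir, files)))
  bad <- files[is.na(actual) | actual != expected]
  if (length(bad))
    stop("checksum mismatch or missing file: ", paste(bad, collapse = ", "))

  out <- list()
  ann_e <- file.path(dir, "annotation_expression.tsv")
  if (file.exists(ann_e)) {
    ann <- read_tsv(ann_e)
    cohorts <- list()
    for (nm in unique(ann$cohort)) {
      sub <- ann[ann$cohort == nm, ]
      expr <- df_to_matrix(read_tsv(file.path(dir, sprintf("expr_%s.tsv", nm))),
                           "gene_id")
      cohorts[[nm]] <- list(name = nm, histology = sub$histology[1],
                            expr = expr[, sub$sample_id, drop = FALSE],
                            groups = sub$group)
    }
    out$expression <- list(
      collection = structure(list(cohorts = cohorts),
                             class = "cohort_collection"))
  }
  if (file.exists(file.path(dir, "beta.tsv"))) {
    ann <- read_tsv(file.path(dir, "annotation_methylation.tsv"),
                    numeric_cols = "seed_expression")
    out$methylation <- list(
      map = as_cpg_map(read_tsv(file.path(dir, "cpg_map.tsv"),
                                numeric_cols = c("start", "end"))),
      beta = df_to_matrix(read_tsv(file.path(dir, "beta.tsv")), "probe_id"),
      groups = ann$group,
      second = list(
        map = as_cpg_map(read_tsv(file.path(dir, "cpg_map_second.tsv"),
                                  numeric_cols = c("start", "end"))),
        beta = df_to_matrix(read_tsv(file.path(dir, "beta_second.tsv")),
                            "probe_id")),
      seed_expression = stats::setNames(ann$seed_expression, ann$sample_id))
  }
  if (file.exists(file.path(dir, "survival.tsv"))) {
    sv <- read_tsv(file.path(dir, "survival.tsv"),
                   numeric_cols = c("dfs_time", "dfs_event", "os_time",
                                    "os_event", "age", "sex", "smoking",
                                    "marker"))
    class(sv) <- c("survival_table", "data.frame")
    out$survival <- sv
  }
  tpath <- file.path(dir, "truth.txt")
  if (file.exists(tpath)) {
    kv <- strsplit(readLines(tpath), "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    out$truth <- structure(list(
      seed_gene = vals[["seed_gene"]],
      planted_gene_ids = strsplit(vals[["planted_gene_ids"]], ",")[[1]],
      planted_region_bounds = c(start = as.integer(vals[["planted_region_start"]]),
                                end = as.integer(vals[["planted_region_end"]])),
      true_coupling = as.numeric(vals[["true_coupling"]]),
      true_log_hr = as.numeric(vals[["true_log_hr"]]),
      rng_seed = as.integer(vals[["rng_seed"]])
    ), class = "synthetic_truth")
  }
  out
}
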