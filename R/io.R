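## TSV / gene-set readers and writers. All outputs carry "#"-prefixed header
## comments (tool version, seed, config hash) and round-trip at full double
## precision.

header_lines <- function(meta = list()) {
  meta <- c(list(tool = paste0("orthoDE ",
                               as.character(utils::packageVersion("orthoDE")))),
            meta)
  paste0("# ", names(meta), ": ", vapply(meta, as.character, character(1)))
}

write_tsv_commented <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(meta), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                quote = "")
  fields <- fields[!is.na(fields)]
  if (length(fields) == 0) stop("empty table: ", path)
  if (length(unique(fields)) > 1) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    bad <- body[which(fields != fields[1])[1]]
    stop("malformed (ragged) row in ", path, " at line ", bad)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a gene-by-sample matrix TSV
#'
#' First column `gene_id`, one column per sample; `#` header comments carry
#' provenance. Values round-trip at full precision.
#'
#' @param matrix an [expr_matrix].
#' @param path output file path.
#' @param meta named list of extra header fields (e.g. seed).
#' @return `write_matrix_tsv`: the path, invisibly. `read_matrix_tsv`: an
#'   [expr_matrix] (requires the matching sample sheet).
#' @export
write_matrix_tsv <- function(matrix, path, meta = list()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, c(meta, list(unit = matrix$unit)))
}

#' @param sheet_path path of the sample sheet TSV (columns `sample_id`,
#'   `species`, `group`, `replicate`).
#' @param unit unit tag of the stored values.
#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, sheet_path, unit = "raw") {
  df <- read_tsv_checked(path)
  sheet <- read_tsv_checked(sheet_path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  sheet$sample_id <- as.character(sheet$sample_id)
  expr_matrix(vals, sheet, unit = unit)
}

#' Write a sample sheet TSV
#'
#' @param matrix an [expr_matrix].
#' @param path output file path.
#' @param meta named list of extra header fields.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(matrix, path, meta = list()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  write_tsv_commented(matrix$samples, path, meta)
}

#' Read / write newline-delimited gene-set files
#'
#' One id per line; `#` comment lines and blank lines are ignored. An empty
#' file is an empty set, not an error.
#'
#' @param ids character vector of gene/group ids.
#' @param path file path.
#' @param meta named list of extra header fields.
#' @return `read_gene_set`: character vector of ids.
#' @export
write_gene_set <- function(ids, path, meta = list()) {
  writeLines(c(header_lines(meta), ids), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Write an orthologue table TSV
#'
#' @param table an [ortholog_table()].
#' @param path output file path.
#' @param meta named list of extra header fields.
#' @return The path, invisibly.
#' @export
write_ortholog_table <- function(table, path, meta = list()) {
  stopifnot(inherits(table, "ortholog_table"))
  write_tsv_commented(as.data.frame(table), path,
                      c(meta, list(species = paste(attr(table, "species"),
                                                   collapse = ","))))
}

#' Write a full simulated study to disk
#'
#' Emits per-species count matrices and sample sheets, the in vitro matrix
#' and sheet, the orthologue table, the truth table and the config (JSON).
#'
#' @param sim an `epiblast_sim` from [simulate_epiblast()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "epiblast_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = sim$config$seed)
  files <- c()
  for (s in names(sim$species)) {
    mp <- file.path(dir, paste0(s, "_counts.tsv"))
    sp <- file.path(dir, paste0(s, "_samples.tsv"))
    write_matrix_tsv(sim$species[[s]], mp, meta)
    write_sample_sheet(sim$species[[s]], sp, meta)
    files <- c(files, mp, sp)
  }
  iv <- file.path(dir, "invitro_counts.tsv")
  ivs <- file.path(dir, "invitro_samples.tsv")
  write_matrix_tsv(sim$invitro, iv, meta)
  write_sample_sheet(sim$invitro, ivs, meta)
  ot <- file.path(dir, "orthologs.tsv")
  write_ortholog_table(sim$orthologs, ot, meta)
  tt <- file.path(dir, "truth.tsv")
  write_tsv_commented(sim$truth, tt, meta)
  cfgp <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cfgp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, iv, ivs, orthologs = ot, truth = tt, config = cfgp))
}
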