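# Readers and writers for the interchange formats: GeneNetwork-style .geno,
# animal-level trait CSV, BED gene annotation (0-based half-open bp), GMT
# gene sets, and probes-by-strains expression TSV. All writers can stamp a
# '#'-prefixed provenance header which all readers skip.

read_lines_data <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a GeneNetwork-style .geno file
#'
#' Tab-delimited; '@'-prefixed metadata lines and '#' comments are skipped;
#' data columns are Chr, Locus, cM, Mb, then one column per strain with calls
#' in B/D/H/U.
#'
#' @param path File path.
#' @param subpop Optional named character vector of sub-population labels per
#'   strain; strains not named get \code{"unknown"}.
#' @return A \code{geno_matrix}.
#' @export
read_geno <- function(path, subpop = NULL) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(@|#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 2) stop("no data rows in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 ||
      !identical(tolower(header[1:4]), c("chr", "locus", "cm", "mb")))
    stop("expected header Chr/Locus/cM/Mb + strain columns in ", path)
  strains <- header[-(1:4)]
  dup <- strains[duplicated(strains)]
  if (length(dup)) stop("duplicated strain column(s): ", paste(dup, collapse = ", "))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("line ", lineno[-1][bad[1]], ": expected ", length(header), " fields")
  M <- do.call(rbind, rows)
  map <- data.frame(marker = M[, 2], chr = M[, 1],
                    cM = as.numeric(M[, 3]), Mb = as.numeric(M[, 4]),
                    stringsAsFactors = FALSE)
  calls <- t(M[, -(1:4), drop = FALSE])
  dimnames(calls) <- list(strains, map$marker)
  ok <- calls %in% c("B", "D", "H", "U")
  if (!all(ok)) {
    i <- which(!matrix(ok, nrow(calls)))[1]
    mk <- (i - 1) %/% nrow(calls) + 1
    stop("unknown genotype code '", calls[i], "' at marker ", map$marker[mk],
         " (line ", lineno[-1][mk], ")")
  }
  sp <- if (is.null(subpop)) stats::setNames(rep("unknown", length(strains)), strains)
  else {
    s <- subpop[strains]
    s[is.na(s)] <- "unknown"
    stats::setNames(s, strains)
  }
  structure(list(calls = calls, map = map, strains = strains, subpop = sp),
            class = "geno_matrix")
}

#' Write a GeneNetwork-style .geno file
#'
#' @param geno A \code{geno_matrix}.
#' @param path File path.
#' @param header Optional extra '#' comment lines (e.g. provenance stamp).
#' @export
write_geno <- function(geno, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(c("@type:riset", "@mat:B", "@pat:D", "@het:H", "@unk:U"), con)
  writeLines(paste(c("Chr", "Locus", "cM", "Mb", geno$strains), collapse = "\t"), con)
  body <- cbind(geno$map$chr, geno$map$marker, geno$map$cM, geno$map$Mb,
                t(geno$calls))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
}

#' Read an animal-level trait CSV
#'
#' Columns: animal_id, strain, sex, battery, trait_id, value. '#' comment
#' lines are skipped; empty values become NA.
#'
#' @param path File path.
#' @return An \code{ri_phenotypes} data frame.
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "strain", "sex", "battery", "trait_id", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(d$sex %in% c("M", "F"))) stop("sex must be M or F")
  d$value <- as.numeric(d$value)
  class(d) <- c("ri_phenotypes", "data.frame")
  d
}

#' Write an animal-level trait CSV
#' @param data \code{ri_phenotypes} data frame.
#' @param path File path.
#' @param header Optional '#' comment lines.
#' @export
write_traits <- function(data, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
}

#' Read a BED gene annotation
#'
#' 0-based half-open bp intervals; a leading "chr" prefix is stripped from
#' chromosome names; coordinates are converted to Mb.
#'
#' @param path File path.
#' @return Gene annotation data frame (\code{gene_id}, \code{chr},
#'   \code{start_Mb}, \code{end_Mb}).
#' @export
read_bed <- function(path) {
  ld <- read_lines_data(path)
  rows <- strsplit(ld$lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 4)
  if (length(bad)) stop("line ", ld$lineno[bad[1]], ": BED needs >= 4 fields")
  M <- do.call(rbind, lapply(rows, `[`, 1:4))
  out <- data.frame(gene_id = M[, 4], chr = sub("^chr", "", M[, 1]),
                    start_Mb = as.numeric(M[, 2]) / 1e6,
                    end_Mb = as.numeric(M[, 3]) / 1e6,
                    stringsAsFactors = FALSE)
  if (any(out$start_Mb >= out$end_Mb)) stop("BED intervals must have start < end")
  out
}

#' Write a BED gene annotation (Mb scaled to bp)
#' @param annotation Gene annotation data frame.
#' @param path File path.
#' @param header Optional '#' comment lines.
#' @export
write_bed <- function(annotation, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("chr%s\t%d\t%d\t%s", annotation$chr,
                     as.integer(round(annotation$start_Mb * 1e6)),
                     as.integer(round(annotation$end_Mb * 1e6)),
                     annotation$gene_id), con)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then gene ids.
#'
#' @param path File path.
#' @return Named list of gene-id vectors with a \code{"descriptions"}
#'   attribute.
#' @export
read_gmt <- function(path) {
  ld <- read_lines_data(path)
  rows <- strsplit(ld$lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3)
  if (length(bad)) stop("line ", ld$lineno[bad[1]],
                        ": GMT rows need name, description and >= 1 gene")
  sets <- lapply(rows, function(r) r[-(1:2)])
  names(sets) <- vapply(rows, `[`, "", 1)
  attr(sets, "descriptions") <- vapply(rows, `[`, "", 2)
  sets
}

#' Write a GMT gene-set file
#' @param sets Named list of gene-id vectors.
#' @param path File path.
#' @param descriptions Per-set descriptions; defaults to the attribute or
#'   the set names.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) descriptions <- names(sets)
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    ""), path)
}

#' Read a probes-by-strains expression TSV
#'
#' First two columns are probe_id and gene_id; remaining columns are strains.
#'
#' @param path File path.
#' @param tissue Tissue label to attach.
#' @return An \code{expr_matrix}.
#' @export
read_expression <- function(path, tissue = "unknown") {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (ncol(d) < 3 || !identical(names(d)[1:2], c("probe_id", "gene_id")))
    stop("expected columns probe_id, gene_id, then strains")
  if (anyDuplicated(d$probe_id)) stop("duplicate probe ids")
  values <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(values) <- d$probe_id
  structure(list(values = values,
                 probes = data.frame(probe_id = d$probe_id,
                                     gene_id = d$gene_id,
                                     stringsAsFactors = FALSE),
                 tissue = tissue),
            class = "expr_matrix")
}

#' Write a probes-by-strains expression TSV
#' @param expr An \code{expr_matrix}.
#' @param path File path.
#' @param header Optional '#' comment lines.
#' @export
write_expression <- function(expr, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  d <- data.frame(probe_id = expr$probes$probe_id,
                  gene_id = expr$probes$gene_id,
                  expr$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write a strain-by-trait mean matrix (GeneNetwork submission layout)
#' @param m Strain rows x trait columns matrix.
#' @param path File path.
#' @param header Optional '#' comment lines.
#' @export
write_strain_means <- function(m, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  d <- data.frame(strain = rownames(m), m, check.names = FALSE)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a strain-by-trait mean matrix written by \code{write_strain_means}
#' @param path File path.
#' @return Numeric matrix with strain rownames.
#' @export
read_strain_means <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
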