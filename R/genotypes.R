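#' Construct and validate a genotype dosage matrix
#'
#' Genotypes are stored as a plain numeric matrix of allele dosages with one
#' row per individual and one column per biallelic marker. Every entry must
#' be 0, 1 or 2 (count of the reference allele); missing values are rejected
#' outright -- impute upstream if your data have gaps.
#'
#' @param x numeric matrix (or object coercible to one) of allele dosages.
#' @param individual_ids optional character vector of row labels; defaults to
#'   existing rownames or `1:n`.
#' @param marker_ids optional character vector of column labels; defaults to
#'   existing colnames or `M1..Mp`.
#' @return a validated numeric matrix with dimnames set.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1, 2), c(2, 1, 0)))
#' @export
genotype_matrix <- function(x, individual_ids = NULL, marker_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("genotype matrix needs at least 2 individuals, got ", n)
  if (p < 1L) stop("genotype matrix needs at least 1 marker")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing genotype at individual ", bad[1L], ", marker ", bad[2L],
         "; missing dosages are not allowed")
  }
  ok_dosage <- x == 0 | x == 1 | x == 2
  if (!all(ok_dosage)) {
    bad <- which(!ok_dosage, arr.ind = TRUE)[1L, ]
    stop("genotype entries must be allele dosages 0, 1 or 2; found ",
         x[bad[1L], bad[2L]], " at individual ", bad[1L],
         ", marker ", bad[2L])
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(x)
    if (is.null(individual_ids)) individual_ids <- as.character(seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(x)
    if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(p))
  }
  if (length(individual_ids) != n)
    stop("individual_ids length ", length(individual_ids),
         " does not match ", n, " rows")
  if (length(marker_ids) != p)
    stop("marker_ids length ", length(marker_ids),
         " does not match ", p, " columns")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  dimnames(x) <- list(as.character(individual_ids), as.character(marker_ids))
  x
}

#' Validate a phenotype vector against a genotype matrix
#'
#' Phenotypes are assumed to be pre-corrected for every fixed effect other
#' than the overall mean.
#'
#' @param y numeric vector of trait values, optionally named with
#'   individual ids.
#' @param genotypes validated genotype matrix the phenotypes pair with.
#' @return named numeric vector in genotype row order.
#' @export
phenotype_vector <- function(y, genotypes) {
  y <- as.numeric(stats::setNames(y, names(y)))
  n <- nrow(genotypes)
  if (length(y) != n)
    stop("phenotype length ", length(y), " does not match ",
         n, " genotyped individuals")
  if (!all(is.finite(y)))
    stop("non-finite phenotype value at position ",
         which(!is.finite(y))[1L])
  if (is.null(names(y))) names(y) <- rownames(genotypes)
  if (!identical(names(y), rownames(genotypes)))
    stop("phenotype ids do not match genotype ids")
  y
}

#' Read a genotype dosage matrix from a delimited file
#'
#' Two dialects are supported. `csv`/`tsv`: a header row of marker ids, then
#' one row per individual whose first field is the individual id and
#' remaining fields are dosages in \{0,1,2\}. `plink-raw`: the space-delimited
#' PLINK `--recode A` dosage format whose six leading columns
#' (FID IID PAT MAT SEX PHENOTYPE) are skipped except for IID, used as the
#' individual id.
#'
#' @param path file path.
#' @param dialect one of `"auto"` (by extension: `.raw` is PLINK RAW,
#'   `.csv` is comma-separated, anything else tab-separated), `"csv"`,
#'   `"tsv"`, `"plink-raw"`.
#' @return validated genotype matrix (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path, dialect = c("auto", "csv", "tsv", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.raw$", path, ignore.case = TRUE)) "plink-raw"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (dialect == "plink-raw") {
    dat <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "",
                        stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e) stop("cannot parse PLINK RAW file ", path, ": ",
                               conditionMessage(e)))
    ped_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(ped_cols %in% names(dat)))
      stop("PLINK RAW file ", path, " lacks pedigree columns: ",
           paste(setdiff(ped_cols, names(dat)), collapse = ", "))
    ids <- as.character(dat$IID)
    dos <- dat[, setdiff(names(dat), ped_cols), drop = FALSE]
    x <- as.matrix(dos)
    storage.mode(x) <- "double"
    if (anyNA(x)) {
      bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop("missing dosage in ", path, " at data line ", bad[1L],
           ", marker column ", colnames(x)[bad[2L]])
    }
    g <- genotype_matrix(x, individual_ids = ids, marker_ids = colnames(x))
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
      stop("genotype file ", path, " is empty or has no data rows")
    header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
    marker_ids <- trimws(header[-1L])
    if (length(marker_ids) < 1L)
      stop("genotype file ", path, ": header has no marker columns")
    n <- length(lines) - 1L
    ids <- character(n)
    x <- matrix(NA_real_, n, length(marker_ids))
    for (i in seq_len(n)) {
      fields <- trimws(strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]])
      if (length(fields) != length(marker_ids) + 1L)
        stop("genotype file ", path, " line ", i + 1L, ": expected ",
             length(marker_ids) + 1L, " fields, found ", length(fields))
      ids[i] <- fields[1L]
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      if (anyNA(vals))
        stop("genotype file ", path, " line ", i + 1L,
             ": missing or non-numeric dosage in column ",
             which(is.na(vals))[1L] + 1L)
      x[i, ] <- vals
    }
    if (anyDuplicated(ids))
      stop("genotype file ", path, ": duplicate individual id ",
           ids[duplicated(ids)][1L])
    g <- tryCatch(
      genotype_matrix(x, individual_ids = ids, marker_ids = marker_ids),
      error = function(e) stop("genotype file ", path, ": ",
                               conditionMessage(e)))
  }
  g
}

#' Read phenotypes and align them to a genotype matrix by individual id
#'
#' Expects a two-column delimited file (individual id, trait value) with an
#' optional header; comma, tab or whitespace separated. The genotype file is
#' the ordering authority: values are joined by id and returned in genotype
#' row order.
#'
#' @param path file path.
#' @param genotypes validated genotype matrix.
#' @return named numeric phenotype vector (see [phenotype_vector()]).
#' @export
read_phenotypes <- function(path, genotypes) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("phenotype file ", path, " is empty")
  split1 <- strsplit(trimws(lines[1L]), "[,\t ]+")[[1L]]
  has_header <- length(split1) >= 2L &&
    is.na(suppressWarnings(as.numeric(split1[2L])))
  if (has_header) lines <- lines[-1L]
  fields <- strsplit(trimws(lines), "[,\t ]+")
  bad_len <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad_len))
    stop("phenotype file ", path, " line ", bad_len[1L] + has_header,
         ": expected id and value")
  ids <- vapply(fields, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(vals))
    stop("phenotype file ", path, ": non-numeric value for id ",
         ids[which(is.na(vals))[1L]])
  if (anyDuplicated(ids))
    stop("phenotype file ", path, ": duplicate id ",
         ids[duplicated(ids)][1L])
  geno_ids <- rownames(genotypes)
  unknown <- setdiff(ids, geno_ids)
  if (length(unknown))
    stop("phenotype file ", path, ": ids not in genotype file: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(geno_ids, ids)
  if (length(missing))
    stop("phenotype file ", path, ": no phenotype for genotyped ids: ",
         paste(missing, collapse = ", "))
  y <- vals[match(geno_ids, ids)]
  names(y) <- geno_ids
  phenotype_vector(y, genotypes)
}

#' Write a genotype matrix to a delimited file
#'
#' @param genotypes validated genotype matrix.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  header <- paste(c("id", colnames(genotypes)), collapse = sep)
  rows <- vapply(seq_len(nrow(genotypes)), function(i)
    paste(c(rownames(genotypes)[i],
            format(genotypes[i, ], trim = TRUE, scientific = FALSE)),
          collapse = sep), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a phenotype vector to a two-column TSV
#'
#' @param y named numeric phenotype vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, path) {
  writeLines(c("id\tvalue",
               paste(names(y), sprintf("%.17g", y), sep = "\t")), path)
  invisible(path)
}
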