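sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a numeric matrix from a TSV/CSV file
#'
#' The delimiter is sniffed (tab, then comma, then whitespace). Files are
#' headerless by default; rows are observations.
#'
#' @param path File path.
#' @param header Does the first line hold column names?
#' @return Numeric matrix.
#' @export
read_numeric_matrix <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_delim(path)
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "numeric", comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  dimnames(m) <- NULL
  m
}

read_label_vector <- function(path, header = FALSE) {
  v <- read_numeric_matrix(path, header = header)
  if (ncol(v) != 1L) stop(path, " must contain a single column of labels")
  as.integer(v[, 1L])
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read all inputs for a permutation run
#'
#' Reads the data (TSV/CSV with observations in rows and tests in columns,
#' or a 4D NIfTI image flattened to N x V over an optional mask), the design
#' and contrast, and the optional block / variance-group columns, and checks
#' that row counts agree.
#'
#' @param data,design,contrast File paths (contrast rows correspond to
#'   design columns; one contrast per column).
#' @param blocks,vg Optional paths to single-column integer files.
#' @param mask Optional NIfTI mask path (image mode only).
#' @param header Do tabular files carry a header line?
#' @param block_mode Block shuffling mode when \code{blocks} is given.
#' @return List with \code{Y}, \code{M}, \code{C}, \code{blocks}, \code{vg},
#'   and \code{image_info} (NULL for tabular data) for write-back.
#' @export
read_inputs <- function(data, design, contrast, blocks = NULL, vg = NULL,
                        mask = NULL, header = FALSE,
                        block_mode = c("within_block", "whole_block")) {
  image_info <- NULL
  if (is_nifti_path(data)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI images requires the RNifti package")
    img <- RNifti::readNifti(data)
    dm <- dim(img)
    if (length(dm) != 4L) stop("image data must be 4D (space x observations)")
    vox <- prod(dm[1:3])
    Ymat <- t(matrix(as.numeric(img), nrow = vox))
    keep <- if (!is.null(mask)) {
      mk <- RNifti::readNifti(mask)
      as.numeric(mk) != 0
    } else colSums(Ymat != 0) > 0
    Y <- Ymat[, keep, drop = FALSE]
    image_info <- list(dim = dm[1:3], keep = keep, reference = data)
  } else {
    Y <- read_numeric_matrix(data, header = header)
  }
  M <- read_numeric_matrix(design, header = header)
  C <- read_numeric_matrix(contrast, header = header)
  if (nrow(Y) != nrow(M))
    stop("data (", data, ") have ", nrow(Y), " rows but design (", design,
         ") has ", nrow(M))
  if (nrow(C) != ncol(M))
    stop("contrast (", contrast, ") has ", nrow(C),
         " rows but the design has ", ncol(M), " columns")
  eb <- NULL
  if (!is.null(blocks)) {
    bl <- read_label_vector(blocks, header = header)
    if (length(bl) != nrow(Y))
      stop("block file ", blocks, " has ", length(bl), " rows, expected ", nrow(Y))
    eb <- exchangeability_blocks(bl, mode = match.arg(block_mode))
  }
  vgv <- NULL
  if (!is.null(vg)) {
    vgv <- read_label_vector(vg, header = header)
    if (length(vgv) != nrow(Y))
      stop("variance-group file ", vg, " has ", length(vgv), " rows, expected ", nrow(Y))
  }
  list(Y = Y, M = M, C = C, blocks = eb, vg = vgv, image_info = image_info)
}

#' Write permutation results
#'
#' Writes \code{<prefix>_results.tsv} with one row per test (index, T0,
#' p_unc, p_fwer, p_fdr and the 1-p "significance" columns), optionally the
#' null distribution of the per-shuffle maximum
#' (\code{<prefix>_tmax.tsv}), a plain-text run log, and, for image input,
#' 1-p maps written back into the input grid.
#'
#' @param fit A \code{permglm} object.
#' @param prefix Output path prefix.
#' @param image_info Image bookkeeping from \code{\link{read_inputs}}.
#' @param save_null Write the Tmax null distribution.
#' @param config Optional named list echoed into the log.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(fit, prefix, image_info = NULL, save_null = FALSE,
                          config = NULL) {
  tab <- fit$table
  out <- cbind(tab,
               sig_unc = 1 - tab$p_unc,
               sig_fwer = 1 - tab$p_fwer,
               sig_fdr = 1 - tab$p_fdr)
  paths <- character(0)
  f <- paste0(prefix, "_results.tsv")
  utils::write.table(format(out, digits = 12, trim = TRUE), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  if (save_null && !is.null(fit$dist$Tmax)) {
    f2 <- paste0(prefix, "_tmax.tsv")
    utils::write.table(data.frame(Tmax = fit$dist$Tmax), f2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, f2)
  }
  logf <- paste0(prefix, "_log.txt")
  lines <- c(
    paste0("method: ", fit$method),
    paste0("statistic: ", fit$stat),
    paste0("J: ", fit$J),
    paste0("generation: ", if (is.null(fit$generation)) "parametric" else fit$generation),
    paste0("unique_shufflings_possible: ", format(fit$n_possible)),
    paste0("seed: ", if (is.null(fit$seed)) "NA" else fit$seed),
    paste0("alpha: ", fit$alpha),
    paste0("fwer_threshold: ", format(fit$fwer_threshold)))
  if (!is.null(config))
    lines <- c(lines, paste0(names(config), ": ", unlist(lapply(config, format))))
  writeLines(lines, logf)
  paths <- c(paths, logf)
  if (!is.null(image_info)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI images requires the RNifti package")
    for (col in c("sig_unc", "sig_fwer", "sig_fdr")) {
      vol <- numeric(prod(image_info$dim))
      vol[image_info$keep] <- out[[col]]
      arr <- array(vol, image_info$dim)
      f3 <- paste0(prefix, "_", col, ".nii.gz")
      RNifti::writeNifti(RNifti::asNifti(arr, reference = RNifti::readNifti(image_info$reference)), f3)
      paths <- c(paths, f3)
    }
  }
  invisible(paths)
}
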