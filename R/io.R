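#' Read and write acquisition scheme files
#'
#' Acquisition schemes are stored as YAML documents with the
#' [acq_grid()] fields (`b_values`, `te_values`, `tr_values`, optional
#' `averages`, `reference_te`, `reference_tr`) plus free-text metadata
#' under `meta`. Reading validates the grid; malformed files fail with an
#' error naming the offending field. Write-then-read round-trips
#' losslessly.
#'
#' Preset schemes reproducing the standard liver/kidney protocols ship
#' with the package under `system.file("extdata/schemes", package =
#' "t2ivim")`: `liver_consensus.yaml` (six consensus b-values, extended TE
#' range) and `invivo_16b_6te.yaml` (16 b-values with per-b averages, TE
#' 47–72 ms).
#'
#' @param path File path, or the bare name of a shipped preset (e.g.
#'   `"liver_consensus"`).
#' @return `load_scheme()`: an [acq_grid()] (metadata in attribute
#'   `"meta"`). `write_scheme()`: the path, invisibly.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "schemes", paste0(path, ".yaml"),
                           package = "t2ivim")
    if (nzchar(shipped)) path <- shipped
  }
  if (!file.exists(path)) stop("scheme file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (field in c("b_values", "te_values"))
    if (is.null(doc[[field]])) stop("field '", field, "': missing")
  grid <- acq_grid(
    b_values = doc$b_values, te_values = doc$te_values,
    tr_values = if (is.null(doc$tr_values)) 4000 else doc$tr_values,
    averages = doc$averages,
    reference_te = if (is.null(doc$reference_te)) min(doc$te_values)
                   else doc$reference_te,
    reference_tr = if (is.null(doc$reference_tr))
                     (if (is.null(doc$tr_values)) 4000 else doc$tr_values[1])
                   else doc$reference_tr)
  attr(grid, "meta") <- doc$meta
  grid
}

#' @rdname load_scheme
#' @param grid An [acq_grid()].
#' @param meta Optional free-text metadata list.
#' @export
write_scheme <- function(grid, path, meta = NULL) {
  stopifnot(inherits(grid, "acq_grid"))
  doc <- list(b_values = grid$b_values, te_values = grid$te_values,
              tr_values = grid$tr_values,
              reference_te = grid$reference_te,
              reference_tr = grid$reference_tr)
  if (!is.null(grid$averages)) doc$averages <- grid$averages
  if (!is.null(meta)) doc$meta <- meta
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read and write long-format signal tables
#'
#' Signal datasets are exchanged as delimited text with columns
#' `b`, `te`, `tr`, `repetition`, `signal` — simple, language-neutral and
#' diff-able. `write_signal_table()` flattens a `signal_dataset` (or a
#' list of repetitions); `read_signal_table()` reconstructs the dataset
#' for a given scheme.
#'
#' @param ds A `signal_dataset`, or a list of them (repetitions).
#' @param path Output/input file path (tab-separated).
#' @return `read_signal_table()`: a `signal_dataset` (with a repetition
#'   dimension if the table has several).
#' @export
write_signal_table <- function(ds, path) {
  reps <- if (inherits(ds, "signal_dataset")) list(ds) else ds
  rows <- lapply(seq_along(reps), function(i) {
    d <- reps[[i]]
    nodes <- expand.grid(b = d$grid$b_values, te = d$grid$te_values,
                         tr = d$grid$tr_values, KEEP.OUT.ATTRS = FALSE)
    nodes$repetition <- i
    nodes$signal <- as.vector(d$values)
    nodes
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @param grid An [acq_grid()] the table must conform to.
#' @param normalization Normalization tag to attach.
#' @export
read_signal_table <- function(path, grid, normalization = "per_reference") {
  tab <- utils::read.delim(path)
  need <- c("b", "te", "tr", "signal")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns ", paste(need, collapse = ", "))
  if (is.null(tab$repetition)) tab$repetition <- 1L
  nreps <- length(unique(tab$repetition))
  nb <- length(grid$b_values); nte <- length(grid$te_values)
  ntr <- length(grid$tr_values)
  if (nrow(tab) != nb * nte * ntr * nreps)
    stop("table has ", nrow(tab), " rows; scheme expects ",
         nb * nte * ntr, " per repetition")
  tab <- tab[order(tab$repetition, match(tab$tr, grid$tr_values),
                   match(tab$te, grid$te_values),
                   match(tab$b, grid$b_values)), ]
  dims <- c(nb, nte, ntr, if (nreps > 1) nreps)
  structure(list(values = array(tab$signal, dim = dims), grid = grid,
                 normalization = normalization, state = NULL),
            class = "signal_dataset")
}

#' Read a 4D NIfTI stack / write parameter maps as NIfTI
#'
#' `read_image_stack()` loads a 4D NIfTI volume whose 4th dimension
#' enumerates the (b, TE) combinations with b varying fastest (all
#' b-values of the first TE, then the next TE, ...) — the same flattening
#' the joint fit uses — and pairs it with an acquisition scheme.
#' `write_maps()` writes one NIfTI per parameter (the input affine is
#' preserved when the maps came from a read stack) plus a tab-separated
#' ROI summary when labels are given.
#'
#' @param path NIfTI file path.
#' @param scheme An [acq_grid()] (or path/preset name for
#'   [load_scheme()]).
#' @param slice For 3D-multivolume files with several slices, which slice
#'   to extract (default: all collapse — file must be y, x, volumes).
#' @return An `image_stack` (the NIfTI affine in attribute `"affine"`).
#' @export
read_image_stack <- function(path, scheme, slice = NULL) {
  if (!inherits(scheme, "acq_grid")) scheme <- load_scheme(scheme)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && !is.null(slice)) arr <- arr[, , slice, ]
  if (length(dim(arr)) != 3L && length(dim(arr)) != 4L)
    stop("expected a (y, x, volumes) or (y, x, z, volumes) NIfTI")
  if (length(dim(arr)) == 4L && dim(arr)[3] == 1L)
    arr <- array(arr, dim = dim(arr)[c(1, 2, 4)])
  nb <- length(scheme$b_values); nte <- length(scheme$te_values)
  nvol <- dim(arr)[length(dim(arr))]
  if (nvol != nb * nte)
    stop("volume-count mismatch: expected ", nb * nte, " (", nb, " b x ",
         nte, " TE), found ", nvol)
  vals <- array(arr, dim = c(dim(arr)[1], dim(arr)[2], nb, nte))
  out <- structure(list(values = vals, grid = scheme, truth = NULL,
                        mask = NULL),
                   class = "image_stack")
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' @rdname read_image_stack
#' @param maps A `"parameter_maps"` object.
#' @param prefix Output path prefix; files are `<prefix>_<param>.nii.gz`.
#' @param labels Optional ROI label matrix for a `<prefix>_roi.tsv`
#'   summary.
#' @param affine Optional 4x4 affine to stamp on the outputs.
#' @return Invisibly, the vector of files written.
#' @export
write_maps <- function(maps, prefix, labels = NULL, affine = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  written <- character(0)
  for (p in names(maps$maps)) {
    m <- maps$maps[[p]]
    if (all(is.na(m))) next
    img <- RNifti::asNifti(array(m, dim = c(dim(m), 1)))
    if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    f <- paste0(prefix, "_", p, ".nii.gz")
    RNifti::writeNifti(img, f)
    written <- c(written, f)
  }
  if (!is.null(labels)) {
    f <- paste0(prefix, "_roi.tsv")
    utils::write.table(roi_summary(maps, labels), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
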