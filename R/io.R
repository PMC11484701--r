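# File formats: HDF5 for complex multi-repetition stacks (complex data is
# stored as paired real/imag datasets), NIfTI (float32) for real-valued 2-D
# images and noise maps.

#' Write / read a repetition stack as HDF5
#'
#' Layout: `/dwi/b{value}/dir{k}/rep{j}/{real,imag}` for the complex
#' repetitions, `/meta/*` for b-values, direction labels, repetition counts
#' and the seed, and (when ground truth is supplied) `/sigma_map` and
#' `/truth/*`.
#'
#' @param stack A `rep_stack`.
#' @param file HDF5 file path (overwritten).
#' @param truth Optional `phantom_truth` stored alongside.
#' @return `read_stack` returns a list with `stack`, `sigma_map` (or
#'   `NULL`) and `truth` (or `NULL`).
#' @export
write_stack <- function(stack, file, truth = NULL) {
  stopifnot(inherits(stack, "rep_stack"))
  if (file.exists(file)) unlink(file)
  rhdf5::h5createFile(file)
  rhdf5::h5createGroup(file, "meta")
  rhdf5::h5write(stack$b_values, file, "meta/b_values")
  rhdf5::h5write(stack$directions, file, "meta/directions")
  rhdf5::h5write(stack$n_repetitions, file, "meta/n_repetitions")
  rhdf5::h5write(as.integer(stack$seed %||% NA_integer_), file, "meta/seed")
  rhdf5::h5createGroup(file, "dwi")
  for (bi in seq_along(stack$b_values)) {
    bg <- sprintf("dwi/b%g", stack$b_values[bi])
    rhdf5::h5createGroup(file, bg)
    for (d in seq_along(stack$directions)) {
      dg <- sprintf("%s/dir%d", bg, d)
      rhdf5::h5createGroup(file, dg)
      reps <- stack$data[[bi]][[d]]
      for (j in seq_len(dim(reps)[3])) {
        rg <- sprintf("%s/rep%d", dg, j)
        rhdf5::h5createGroup(file, rg)
        rhdf5::h5write(Re(reps[, , j]), file, paste0(rg, "/real"))
        rhdf5::h5write(Im(reps[, , j]), file, paste0(rg, "/imag"))
      }
    }
  }
  if (!is.null(truth)) {
    rhdf5::h5write(truth$sigma_map, file, "sigma_map")
    rhdf5::h5createGroup(file, "truth")
    rhdf5::h5write(truth$s0, file, "truth/s0")
    rhdf5::h5write(truth$adc, file, "truth/adc")
    rhdf5::h5write(truth$phase_bg, file, "truth/phase_bg")
    rhdf5::h5createGroup(file, "truth/clean")
    for (bi in seq_along(stack$b_values))
      rhdf5::h5write(truth$clean[[bi]], file,
                     sprintf("truth/clean/b%g", stack$b_values[bi]))
  }
  rhdf5::h5closeAll()
  invisible(file)
}

h5_exists <- function(file, name) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::h5closeAll())
  rhdf5::H5Lexists(fid, name)
}

#' @rdname write_stack
#' @param sigma_required Error if `/sigma_map` is absent? Set `FALSE` for
#'   stacks whose noise map will be estimated from repetitions or supplied
#'   externally.
#' @export
read_stack <- function(file, sigma_required = TRUE) {
  if (!file.exists(file)) stop("no such file: ", file)
  for (nm in c("meta/b_values", "meta/directions", "meta/n_repetitions"))
    if (!h5_exists(file, nm))
      stop("malformed stack file: missing dataset /", nm)
  b_values <- as.numeric(rhdf5::h5read(file, "meta/b_values"))
  directions <- as.character(rhdf5::h5read(file, "meta/directions"))
  n_reps <- as.integer(rhdf5::h5read(file, "meta/n_repetitions"))
  seed <- tryCatch(as.integer(rhdf5::h5read(file, "meta/seed")),
                   error = function(e) NA_integer_)
  data <- vector("list", length(b_values))
  H <- W <- NULL
  for (bi in seq_along(b_values)) {
    data[[bi]] <- vector("list", length(directions))
    for (d in seq_along(directions)) {
      reps <- NULL
      for (j in seq_len(n_reps[bi])) {
        rg <- sprintf("dwi/b%g/dir%d/rep%d", b_values[bi], d, j)
        if (!h5_exists(file, paste0(rg, "/real")))
          stop("malformed stack file: missing dataset /", rg, "/real")
        re <- rhdf5::h5read(file, paste0(rg, "/real"))
        im <- rhdf5::h5read(file, paste0(rg, "/imag"))
        if (is.null(reps)) {
          H <- nrow(re); W <- ncol(re)
          reps <- array(0i, c(H, W, n_reps[bi]))
        }
        reps[, , j] <- re + 1i * im
      }
      data[[bi]][[d]] <- reps
    }
  }
  sigma_map <- NULL
  if (h5_exists(file, "sigma_map")) {
    sigma_map <- rhdf5::h5read(file, "sigma_map")
  } else if (sigma_required) {
    stop("missing dataset /sigma_map in ", file,
         " (pass sigma_required = FALSE to read without it)")
  }
  truth <- NULL
  if (h5_exists(file, "truth")) {
    clean <- lapply(b_values, function(b)
      rhdf5::h5read(file, sprintf("truth/clean/b%g", b)))
    truth <- structure(list(s0 = rhdf5::h5read(file, "truth/s0"),
                            adc = rhdf5::h5read(file, "truth/adc"),
                            phase_bg = rhdf5::h5read(file, "truth/phase_bg"),
                            phase_rep = NULL, sigma_map = sigma_map,
                            clean = clean, b_values = b_values,
                            directions = directions),
                       class = "phantom_truth")
  }
  rhdf5::h5closeAll()
  stack <- structure(list(data = data, b_values = b_values,
                          directions = directions, H = H, W = W,
                          n_repetitions = n_reps, seed = seed),
                     class = "rep_stack")
  list(stack = stack, sigma_map = sigma_map, truth = truth)
}

#' Write / read a 2-D image or noise map as NIfTI
#'
#' Images are stored as single-slice float32 volumes; the round trip is
#' exact for values already representable in float32.
#'
#' @param map Real matrix.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_map` returns a matrix.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  RNifti::writeNifti(RNifti::asNifti(array(map, c(dim(map), 1L))),
                     path, datatype = "float")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1L]
  matrix(as.numeric(arr), nrow(arr), ncol(arr))
}
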