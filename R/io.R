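#' Convert a voxel table to a matrix image
#'
#' @param maps Data frame with `x`, `y` and `field`.
#' @param field Column name.
#' @param fill Value for grid positions absent from the table.
#' @return Numeric matrix indexed `[x, y]`.
#' @export
map_to_matrix <- function(maps, field, fill = NA_real_) {
  nx <- max(maps$x); ny <- max(maps$y)
  m <- matrix(fill, nx, ny)
  m[cbind(maps$x, maps$y)] <- maps[[field]]
  m
}

#' Write / read parameter maps as NIfTI volumes
#'
#' One single-slice NIfTI file per field, named `<field>.nii.gz`.
#'
#' @param maps Voxel table (e.g. [assemble_maps()] output).
#' @param dir Output directory (created if needed).
#' @param fields Map columns to write.
#' @param voxel_mm In-plane voxel size recorded in the header, mm.
#' @return `write_maps_nifti()` the directory, invisibly;
#'   `read_map_nifti()` a tibble with `x`, `y`, `value`.
#' @export
write_maps_nifti <- function(maps, dir,
                             fields = intersect(c("T1", "T2", "PD", "B0_hz",
                                                  "B1", "HO", "phase",
                                                  "signal"),
                                                names(maps)),
                             voxel_mm = 1.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in fields) {
    img <- map_to_matrix(maps, f)
    arr <- array(img, dim = c(dim(img), 1L))
    RNifti::writeNifti(
      RNifti::asNifti(arr, pixdim = c(voxel_mm, voxel_mm, 1)),
      file.path(dir, paste0(f, ".nii.gz")), datatype = "double"
    )
  }
  invisible(dir)
}

#' @rdname write_maps_nifti
#' @param path NIfTI file path.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- drop(as.array(img))
  tidyr::expand_grid(x = seq_len(nrow(arr)), y = seq_len(ncol(arr))) |>
    dplyr::mutate(value = arr[cbind(.data$x, .data$y)])
}

#' Write / read a simulated dataset
#'
#' The complex echo trains are stored as two NIfTI volumes
#' (`echoes_re.nii.gz`, `echoes_im.nii.gz`; dimensions x, y, echo), the
#' phantom as `phantom.csv`, the block as `block.yaml`, and the
#' acquisition metadata (`n_blocks`, `sigma`, `seed`, `tr_ip`) as a JSON
#' sidecar `dataset.json`.
#'
#' @param dataset An [simulate_dataset()] result.
#' @param dir Output directory.
#' @return `write_dataset()` the directory invisibly; `read_dataset()` an
#'   `mp_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- dataset$phantom
  nx <- max(ph$x); ny <- max(ph$y)
  n_echo <- nrow(dataset$echoes)
  re <- array(0, c(nx, ny, n_echo))
  im <- array(0, c(nx, ny, n_echo))
  for (k in seq_len(n_echo)) {
    re[, , k][cbind(ph$x, ph$y)] <- Re(dataset$echoes[k, ])
    im[, , k][cbind(ph$x, ph$y)] <- Im(dataset$echoes[k, ])
  }
  RNifti::writeNifti(RNifti::asNifti(re), file.path(dir, "echoes_re.nii.gz"),
                     datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(im), file.path(dir, "echoes_im.nii.gz"),
                     datatype = "double")
  utils::write.csv(tibble::as_tibble(ph), file.path(dir, "phantom.csv"),
                   row.names = FALSE)
  write_block_yaml(dataset$block, file.path(dir, "block.yaml"))
  jsonlite::write_json(
    list(n_blocks = dataset$n_blocks, sigma = dataset$sigma,
         seed = dataset$seed, tr_ip = dataset$tr_ip),
    file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  re <- as.array(RNifti::readNifti(file.path(dir, "echoes_re.nii.gz")))
  im <- as.array(RNifti::readNifti(file.path(dir, "echoes_im.nii.gz")))
  ph <- tibble::as_tibble(utils::read.csv(file.path(dir, "phantom.csv")))
  class(ph) <- c("mp_phantom", class(ph))
  n_echo <- dim(re)[3]
  echoes <- matrix(0 + 0i, n_echo, nrow(ph))
  for (k in seq_len(n_echo)) {
    echoes[k, ] <- complex(real = re[, , k][cbind(ph$x, ph$y)],
                           imaginary = im[, , k][cbind(ph$x, ph$y)])
  }
  structure(
    list(echoes = echoes, phantom = ph,
         block = read_block_yaml(file.path(dir, "block.yaml")),
         n_blocks = meta$n_blocks, sigma = meta$sigma, seed = meta$seed,
         tr_ip = meta$tr_ip),
    class = "mp_dataset"
  )
}

#' Write a machine-readable run manifest
#'
#' @param dir Output directory.
#' @param params Named list of run parameters (must include any seed).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, params) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "mpbnssfp",
           version = as.character(utils::packageVersion("mpbnssfp")),
           timestamp = format(Sys.time(), tz = "UTC")),
      params),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
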