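#' Save and load rendered image stacks
#'
#' A stack is written as a set of NIfTI volumes sharing a path prefix plus a
#' JSON sidecar holding the acquisition metadata. The complex stacks are
#' stored losslessly as real/imaginary float64 volumes
#' (`<prefix>_real_comp.nii`, `_imag_comp.nii`, `_real_enc.nii`,
#' `_imag_enc.nii`); conventional magnitude/phase volumes per encoding
#' (`_mag_*.nii`, `_phase_*.nii`, phase wrapped to `(-pi, pi]`) are written
#' alongside for viewers, and ground-truth maps as `_truth_bg.nii` /
#' `_truth_vel.nii`. `load_stack()` reconstructs the stack from the
#' real/imaginary volumes and validates the sidecar, naming any missing
#' metadata field.
#'
#' @param stack A `pc_stack` from [render_timeseries()].
#' @param prefix Path prefix (directory must exist).
#' @return `save_stack()` returns `prefix` invisibly; `load_stack()`
#'   returns a `pc_stack`.
#' @export
save_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "pc_stack"))
  wn <- function(a, tag) RNifti::writeNifti(
    RNifti::asNifti(a, datatype = "double"),
    paste0(prefix, "_", tag, ".nii"), datatype = "double")
  wn(Re(stack$comp), "real_comp"); wn(Im(stack$comp), "imag_comp")
  wn(Re(stack$enc), "real_enc"); wn(Im(stack$enc), "imag_enc")
  wn(Mod(stack$comp), "mag_comp"); wn(wrap_pi(Arg(stack$comp)), "phase_comp")
  wn(Mod(stack$enc), "mag_enc"); wn(wrap_pi(Arg(stack$enc)), "phase_enc")
  wn(stack$truth_bg, "truth_bg"); wn(stack$truth_vel, "truth_vel")
  meta <- list(
    venc = stack$venc, tr = stack$tr, te = stack$te,
    contrast = stack$contrast, interleave = stack$interleave,
    phases_ms = stack$phases_ms,
    encodings = c("compensated", "encoded"),
    dims = dim(stack$comp),
    fov_mm = stack$grid$fov_mm,
    noise_sigma = stack$noise_sigma, seed = stack$seed)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname save_stack
#' @export
load_stack <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side))
    abort(sprintf("Sidecar not found: %s", side), class = "pcsteady_parse_error")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("venc", "tr", "te", "contrast", "interleave", "phases_ms",
              "dims", "fov_mm"))
    if (is.null(meta[[f]]))
      abort(sprintf("Sidecar field missing: '%s'", f),
            class = "pcsteady_parse_error")
  rd <- function(tag) {
    a <- RNifti::readNifti(paste0(prefix, "_", tag, ".nii"))
    array(as.numeric(a), dim = meta$dims)
  }
  comp <- complex(real = rd("real_comp"), imaginary = rd("imag_comp"))
  enc <- complex(real = rd("real_enc"), imaginary = rd("imag_enc"))
  dim(comp) <- meta$dims; dim(enc) <- meta$dims
  grid <- image_grid(meta$dims[2], meta$dims[1], meta$fov_mm)
  structure(list(
    comp = comp, enc = enc, phases_ms = meta$phases_ms,
    truth_bg = matrix(as.numeric(RNifti::readNifti(paste0(prefix, "_truth_bg.nii"))),
                      meta$dims[1], meta$dims[2]),
    truth_vel = rd("truth_vel"),
    grid = grid, venc = meta$venc, tr = meta$tr, te = meta$te,
    contrast = meta$contrast, interleave = meta$interleave,
    noise_sigma = meta$noise_sigma %||% 0, seed = meta$seed %||% NA_integer_
  ), class = "pc_stack")
}
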