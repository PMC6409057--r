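#' Run the full segmentation pipeline from a configuration
#'
#' Stages: obtain the input (generate a phantom, or read a volume and crop
#' the volume of interest), build the classifier, select the initialization,
#' evolve the level set, and evaluate against the ground truth when
#' available. All artifacts (mask, per-iteration trace, metrics, config echo)
#' are written to the output directory, which is self-describing: the config
#' echo plus the seed reproduce the run bit-identically in oracle mode.
#'
#' Configuration (a named list, or the path of a YAML file with the same
#' structure):
#' \describe{
#'   \item{seed}{integer, used for every random draw.}
#'   \item{out_dir}{output directory (created if missing).}
#'   \item{phantom}{optional [phantom_spec()] arguments; generates the input.}
#'   \item{input}{alternatively, `volume` (NIfTI path), optional `gt`, and a
#'     required `voi` = `c(x0, y0, z0, x1, y1, z1)` (0-based, half-open)
#'     bounding box. No automatic tumor detection is attempted.}
#'   \item{energy}{[energy_config()] arguments.}
#'   \item{regulation}{[regulation_config()] arguments.}
#'   \item{classifier}{`"oracle"`, `"none"`, or `"cnn:<checkpoint.rds>"`.}
#'   \item{init}{`candidate_radii` for the automatic initialization, or a
#'     fixed `radius` when `classifier = "none"` (default 10).}
#' }
#'
#' @param config named list or YAML path.
#' @return List with `result` ([evolve()] output), `metrics` (or `NULL`),
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must name an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  # --- input ---
  gt <- NULL
  inp <- stage("input", {
    if (!is.null(cfg$phantom)) {
      ph_args <- cfg$phantom
      if (is.null(ph_args$seed)) ph_args$seed <- seed
      ph <- generate_phantom(do.call(phantom_spec, ph_args))
      gt <- ph$gt_mask
      f <- file.path(out_dir, "volume.nii.gz")
      write_volume(ph$volume, f)
      files <- c(files, f)
      g <- file.path(out_dir, "gt_mask.nii.gz")
      write_mask(ph$gt_mask, g, spacing = ph$volume$spacing)
      files <- c(files, g)
      ph$volume
    } else if (!is.null(cfg$input)) {
      if (is.null(cfg$input$voi)) {
        stop("a volume of interest (`input$voi`) is required; ",
             "no automatic tumor detection is performed")
      }
      vol <- read_volume(cfg$input$volume)
      voi <- as.integer(cfg$input$voi)
      if (length(voi) != 6) stop("`voi` must be x0,y0,z0,x1,y1,z1")
      sel <- list((voi[1] + 1):voi[4], (voi[2] + 1):voi[5], (voi[3] + 1):voi[6])
      cropped <- vol$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
      if (!is.null(cfg$input$gt)) {
        gtv <- read_volume(cfg$input$gt)
        gt <- as_mask(gtv$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
      }
      scalar_volume(cropped, spacing = vol$spacing, origin = vol$origin)
    } else {
      stop("config must contain either `phantom` or `input`")
    }
  })

  energy <- do.call(energy_config, as.list(cfg$energy))
  regulation <- do.call(regulation_config, as.list(cfg$regulation))

  cls_name <- if (is.null(cfg$classifier)) "oracle" else cfg$classifier
  classifier <- stage("classifier", {
    if (identical(cls_name, "none")) NULL
    else if (identical(cls_name, "oracle")) {
      if (is.null(gt)) stop("the oracle classifier needs a ground-truth mask")
      oracle_classifier(gt, regulation$sigma_frac)
    } else if (startsWith(cls_name, "cnn:")) {
      net <- readRDS(sub("^cnn:", "", cls_name))
      cnn_classifier(net)
    } else stop("unknown classifier '", cls_name, "'")
  })

  phi0 <- stage("initialization", {
    d <- dim(inp$data)
    center <- if (is.null(cfg$init$center)) (d + 1) / 2 else cfg$init$center
    if (is.null(classifier)) {
      r <- if (is.null(cfg$init$radius)) 10 else cfg$init$radius
      init_sdf_ball(d, center, r)
    } else {
      radii <- if (is.null(cfg$init$candidate_radii)) {
        regulation$candidate_radii
      } else cfg$init$candidate_radii
      select_initialization(inp, center, radii, classifier)$phi
    }
  })

  res <- stage("evolution", {
    evolve(inp, phi0, energy, classifier, gt_mask = gt,
           regulation = regulation)
  })

  f <- file.path(out_dir, "mask.nii.gz")
  write_mask(res$mask, f, spacing = inp$spacing, origin = inp$origin)
  files <- c(files, f)
  f <- file.path(out_dir, "trace.csv")
  write.csv(res$trace, f, row.names = FALSE)
  files <- c(files, f)

  metrics <- NULL
  if (!is.null(gt)) {
    metrics <- stage("evaluation", metric_report(res$mask, gt, inp$spacing))
    f <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(as.list(metrics), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  echo <- cfg
  echo$seed <- seed
  f <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(echo, f)
  files <- c(files, f)

  list(result = res, metrics = metrics, files = files)
}
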