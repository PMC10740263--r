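#' Model registry
#'
#' Trained models live in a registry directory, one subdirectory per model,
#' containing the profile text file, a metadata JSON (name, alphabet size,
#' match-column IMGT labels, provenance) and the source alignment in
#' Stockholm dialect.  The registry directory is the single source of truth
#' for [listModels()] / [removeModel()].
#'
#' @name germline_model
#' @keywords internal
NULL

#' Registry directory resolution
#'
#' Resolution order: explicit argument > `options(igprofile.registry=)` >
#' `IGPROFILE_REGISTRY` environment variable > the per-user data directory
#' `tools::R_user_dir("igprofile", "data")/models`.
#'
#' @param registry explicit path or NULL.
#' @return normalised registry path (not necessarily existing yet).
#' @export
registryPath <- function(registry = NULL) {
  if (!is.null(registry)) return(registry)
  opt <- getOption("igprofile.registry")
  if (!is.null(opt)) return(opt)
  env <- Sys.getenv("IGPROFILE_REGISTRY", "")
  if (nzchar(env)) return(env)
  file.path(tools::R_user_dir("igprofile", "data"), "models")
}

#' Build and register an annotation model
#'
#' Validates the alignment (refusing on structural failures), trains the
#' profile HMM in the requested alphabet, and stores profile + metadata +
#' source alignment under `registry/name/`.  The stored model is immediately
#' usable by [annotate()]; queries are automatically reduced with the same
#' alphabet the model was trained in.
#'
#' @param aln a [ModelAlignment-class] (from [buildAlignment()] or
#'   [importAlignment()]).
#' @param name model name, matching `[A-Za-z0-9_.-]+`.
#' @param alphabetSize alphabet size 3..20 (default 20 = no reduction).
#' @param registry registry directory (see [registryPath()]).
#' @param overwrite replace an existing model of the same name.
#' @return the [ProfileModel-class], invisibly.
#' @export
buildModel <- function(aln, name, alphabetSize = 20, registry = NULL,
                       overwrite = FALSE) {
  registry <- registryPath(registry)
  if (!grepl("^[A-Za-z0-9_.-]+$", name))
    stop("invalid model name '", name,
         "': use only letters, digits, '_', '.', '-'", call. = FALSE)
  rep <- validateAlignment(aln)
  if (!rep$pass) {
    fails <- rep$findings[rep$findings$level == "fail", ]
    stop("alignment failed validation: ",
         paste(fails$code, fails$detail, sep = ":", collapse = ", "),
         call. = FALSE)
  }
  dir <- file.path(registry, name)
  if (dir.exists(dir) && !overwrite)
    stop("model '", name, "' already exists in the registry ",
         "(use overwrite = TRUE to replace it)", call. = FALSE)
  trained <- trainProfile(aln, alphabetSize)
  labels <- aln@labels[trained$matchCols]
  regions <- aln@regions[trained$matchCols]

  # anchor conservation inside the model, reused by consensus validation
  mat <- do.call(rbind, strsplit(aln@rows, "", fixed = TRUE))
  anchorCons <- numeric(0)
  for (a in c("23", "104")) {
    ci <- match(a, aln@labels)
    if (!is.na(ci)) {
      col <- mat[, ci]; col <- col[col != "-"]
      anchorCons[a] <- if (length(col)) mean(col == "C") else 0
    }
  }

  model <- new("ProfileModel", name = name,
               alphabetSize = as.integer(alphabetSize),
               profile = trained$profile, columnLabels = labels,
               columnRegions = regions, anchorConservation = anchorCons,
               provenance = list(built = format(Sys.time(), tz = "UTC"),
                                 nRows = length(aln@rows),
                                 alphabetSize = as.integer(alphabetSize)))
  # stage into a temp dir, then move: entries are complete or absent
  stage <- paste0(dir, ".tmp")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  writeProfile(trained$profile, file.path(stage, "profile.txt"))
  writeAlignment(aln, file.path(stage, "alignment.sto"))
  meta <- list(name = name, alphabet_size = as.integer(alphabetSize),
               n_match = trained$profile@nMatch,
               column_labels = labels, column_regions = regions,
               anchor_conservation = as.list(anchorCons),
               built = model@provenance$built,
               alignment_md5 = unname(tools::md5sum(
                 file.path(stage, "alignment.sto"))))
  jsonlite::write_json(meta, file.path(stage, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  if (!file.rename(stage, dir))
    stop("cannot write model to registry at ", dir, call. = FALSE)
  invisible(model)
}

#' Load a registered model
#'
#' @param name model name.
#' @param registry registry directory.
#' @return a [ProfileModel-class].
#' @export
loadModel <- function(name, registry = NULL) {
  registry <- registryPath(registry)
  dir <- file.path(registry, name)
  if (!dir.exists(dir))
    stop("model '", name, "' not found in registry ", registry, call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  profile <- readProfile(file.path(dir, "profile.txt"))
  new("ProfileModel", name = meta$name,
      alphabetSize = as.integer(meta$alphabet_size), profile = profile,
      columnLabels = as.character(meta$column_labels),
      columnRegions = as.character(meta$column_regions),
      anchorConservation = unlist(meta$anchor_conservation),
      provenance = list(built = meta$built,
                        alignment_md5 = meta$alignment_md5))
}

#' List registered models
#'
#' @param registry registry directory.
#' @return data.frame with columns `name`, `alphabet_size`, `n_match`,
#'   `built`, `corrupt`; zero rows for a fresh registry.  A registry entry
#'   whose metadata cannot be parsed is listed with `corrupt = TRUE` rather
#'   than raising an error.
#' @export
listModels <- function(registry = NULL) {
  registry <- registryPath(registry)
  out <- data.frame(name = character(0), alphabet_size = integer(0),
                    n_match = integer(0), built = character(0),
                    corrupt = logical(0), stringsAsFactors = FALSE)
  if (!dir.exists(registry)) return(out)
  for (d in sort(list.dirs(registry, recursive = FALSE))) {
    name <- basename(d)
    row <- tryCatch({
      meta <- jsonlite::read_json(file.path(d, "meta.json"),
                                  simplifyVector = TRUE)
      stopifnot(file.exists(file.path(d, "profile.txt")))
      data.frame(name = meta$name, alphabet_size = as.integer(meta$alphabet_size),
                 n_match = as.integer(meta$n_match), built = meta$built,
                 corrupt = FALSE, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(name = name, alphabet_size = NA_integer_,
                 n_match = NA_integer_, built = NA_character_,
                 corrupt = TRUE, stringsAsFactors = FALSE))
    out <- rbind(out, row)
  }
  out
}

#' Remove a registered model
#'
#' @param name model name.
#' @param registry registry directory.
#' @return TRUE invisibly on success; a missing name is an error and leaves
#'   the registry untouched.
#' @export
removeModel <- function(name, registry = NULL) {
  registry <- registryPath(registry)
  dir <- file.path(registry, name)
  if (!dir.exists(dir))
    stop("model '", name, "' not found in registry ", registry, call. = FALSE)
  unlink(dir, recursive = TRUE)
  invisible(TRUE)
}

#' @describeIn ProfileModel-class display summary
#' @param object a ProfileModel
#' @export
setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel '", object@name, "': ", object@profile@nMatch,
      " match states, alphabet size ", object@alphabetSize, "\n", sep = "")
  cat("  IMGT columns ", object@columnLabels[[1]], "..",
      object@columnLabels[[length(object@columnLabels)]], "\n", sep = "")
})

#' Model accessors
#'
#' @param x a [ProfileModel-class]
#' @return `modelName`: the registry name; `alphabetSize`: the training
#'   alphabet size; `columnLabels`: IMGT labels of the match states.
#' @export
modelName <- function(x) x@name

#' @rdname modelName
#' @export
alphabetSize <- function(x) x@alphabetSize

#' @rdname modelName
#' @export
columnLabels <- function(x) x@columnLabels
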