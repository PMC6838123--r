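# lossless double <-> string conversion for archives (17 significant
# digits round-trips IEEE-754 doubles exactly; jsonlite's own numeric
# serialisation caps at 15)
num2str <- function(x) sprintf("%.17g", as.numeric(x))
str2num <- function(s) as.numeric(s)

#' Save a fitted model as a self-describing JSON archive
#'
#' Serialises layer sizes, activation schedule, dropout schedule, weights,
#' biases, grids and the run manifest at full floating-point precision, so
#' the archive round-trips exactly through [read_subcomp_model()].
#'
#' @param model A `subcomp_model`.
#' @param path Output path (conventionally `.json` or `.json.gz`).
#' @export
write_subcomp_model <- function(model, path) {
  stopifnot(inherits(model, "subcomp_model"))
  ser_side <- function(side) list(
    autoencoder = list(net = ser_net_json(side$autoencoder$net),
                       sizes = side$autoencoder$sizes,
                       latent_index = side$autoencoder$latent_index,
                       history = side$autoencoder$history),
    classifier = list(net = ser_net_json(side$classifier$net),
                      sizes = side$classifier$sizes,
                      center = num2str(side$classifier$center),
                      scale = num2str(side$classifier$scale),
                      history = side$classifier$history),
    train_bins = side$train_bins)
  obj <- list(format = "hicsubcomp_model", version = 1L,
              manifest = model$manifest,
              row_grid = list(bins = as.list(as.data.frame(model$row_grid)),
                              bin_size = attr(model$row_grid, "bin_size"),
                              parity = attr(model$row_grid, "parity")),
              col_grid = list(bins = as.list(as.data.frame(model$col_grid)),
                              bin_size = attr(model$col_grid, "bin_size"),
                              parity = attr(model$col_grid, "parity")),
              odd = ser_side(model$odd), even = ser_side(model$even))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), con)
  invisible(path)
}

#' Read a model archive written by [write_subcomp_model()]
#'
#' @param path Archive path.
#' @return A `subcomp_model`.
#' @export
read_subcomp_model <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  obj <- jsonlite::fromJSON(readLines(con), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  close(con)
  if (!identical(obj$format, "hicsubcomp_model"))
    stop("not a hicsubcomp model archive: ", path)
  de_net <- de_net_json
  de_grid <- function(g) {
    bins <- as.data.frame(g$bins, stringsAsFactors = FALSE)
    bins$start <- as.numeric(bins$start)
    bins$end <- as.numeric(bins$end)
    structure(bins, bin_size = g$bin_size, parity = g$parity,
              class = c("bin_grid", "data.frame"))
  }
  de_side <- function(s) list(
    autoencoder = structure(list(net = de_net(s$autoencoder$net),
                                 sizes = as.integer(s$autoencoder$sizes),
                                 latent = s$autoencoder$sizes[
                                   s$autoencoder$latent_index],
                                 latent_index = s$autoencoder$latent_index,
                                 trained = TRUE,
                                 history = as.numeric(s$autoencoder$history)),
                            class = "hic_autoencoder"),
    classifier = structure(list(net = de_net(s$classifier$net),
                                sizes = as.integer(s$classifier$sizes),
                                center = str2num(s$classifier$center),
                                scale = str2num(s$classifier$scale),
                                history = as.numeric(s$classifier$history)),
                           class = "subcomp_classifier"),
    train_bins = as.integer(s$train_bins))
  structure(list(odd = de_side(obj$odd), even = de_side(obj$even),
                 row_grid = de_grid(obj$row_grid),
                 col_grid = de_grid(obj$col_grid),
                 manifest = obj$manifest),
            class = "subcomp_model")
}

# shared (de)serialisers for single networks
ser_net_json <- function(net) list(
  sizes = net$sizes, act = net$act, dropout = net$dropout,
  input_activation = net$input_activation,
  W = lapply(net$W, function(w) list(dim = dim(w), data = num2str(w))),
  b = lapply(net$b, num2str))

de_net_json <- function(s) list(
  sizes = as.integer(s$sizes), act = as.character(s$act),
  dropout = as.numeric(s$dropout),
  input_activation = as.character(s$input_activation),
  W = lapply(s$W, function(w) matrix(str2num(w$data), w$dim[1], w$dim[2])),
  b = lapply(s$b, str2num))

write_json_archive <- function(obj, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), con)
  invisible(path)
}

read_json_archive <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  jsonlite::fromJSON(readLines(con), simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Save / load a single trained autoencoder
#'
#' Standalone archives for one network (the full-model archive of
#' [write_subcomp_model()] embeds the same representation).
#'
#' @param ae A `hic_autoencoder`.
#' @param path Archive path (`.json` / `.json.gz`).
#' @return The path (write) or the restored object (read).
#' @export
write_autoencoder <- function(ae, path) {
  stopifnot(inherits(ae, "hic_autoencoder"))
  write_json_archive(list(format = "hicsubcomp_autoencoder",
                          net = ser_net_json(ae$net), sizes = ae$sizes,
                          latent_index = ae$latent_index,
                          history = ae$history, loss = ae$loss), path)
}

#' @rdname write_autoencoder
#' @export
read_autoencoder <- function(path) {
  s <- read_json_archive(path)
  if (!identical(s$format, "hicsubcomp_autoencoder"))
    stop("not an autoencoder archive: ", path)
  structure(list(net = de_net_json(s$net), sizes = as.integer(s$sizes),
                 latent = s$sizes[s$latent_index],
                 latent_index = s$latent_index, trained = TRUE,
                 history = as.numeric(s$history), loss = s$loss),
            class = "hic_autoencoder")
}

#' Save / load a single trained classifier
#'
#' @param clf A `subcomp_classifier`.
#' @param path Archive path (`.json` / `.json.gz`).
#' @return The path (write) or the restored object (read).
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "subcomp_classifier"))
  write_json_archive(list(format = "hicsubcomp_classifier",
                          net = ser_net_json(clf$net), sizes = clf$sizes,
                          center = num2str(clf$center),
                          scale = num2str(clf$scale),
                          history = clf$history), path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  s <- read_json_archive(path)
  if (!identical(s$format, "hicsubcomp_classifier"))
    stop("not a classifier archive: ", path)
  structure(list(net = de_net_json(s$net), sizes = as.integer(s$sizes),
                 center = str2num(s$center), scale = str2num(s$scale),
                 history = as.numeric(s$history)),
            class = "subcomp_classifier")
}
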