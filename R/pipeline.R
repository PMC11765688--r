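#' Pipeline configuration
#'
#' One structured object drives every stage: canonical image size, descriptor
#' parameters, which deep-feature plugins to include, per-block mRMR target
#' sizes (defaults 400 for HOG, 500 for LBP, 400 per deep block, giving the
#' default fused width 1700), the selection criterion and discretization bin
#' count, similarity metrics, retrieval depth, recall denominator, the
#' phantom-generator settings, and the seed.
#'
#' @param working_size canonical image side, px.
#' @param hog a [hog_params()].
#' @param lbp an [lbp_params()].
#' @param deep character vector of deep plugin names (see
#'   [builtin_extractor()]); may be empty.
#' @param reduce named list/vector of per-block selected sizes keyed by
#'   descriptor id (`hog`, `lbp`, `deep:<name>`); missing entries get the
#'   defaults above.
#' @param criterion mRMR criterion, `"MID"` or `"MIQ"`.
#' @param bins mRMR discretization bins.
#' @param metrics similarity metrics to use.
#' @param k retrieval depth.
#' @param denominator recall denominator convention.
#' @param phantom a [phantom_config()].
#' @param seed pipeline seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(working_size = 224, hog = hog_params(),
                            lbp = lbp_params(),
                            deep = c("pool32", "gradpool32"),
                            reduce = NULL, criterion = "MID", bins = 10L,
                            metrics = c("euclidean", "psnr"), k = 20L,
                            denominator = "retrieved",
                            phantom = phantom_config(), seed = 1L) {
  if (!is_count(working_size)) stopf("working_size must be a positive integer")
  if (working_size %% hog$cell_px != 0L)
    stopf("hog cell_px must divide working_size")
  if (working_size %% lbp$grid != 0L)
    stopf("lbp grid must divide working_size")
  deep <- as.character(deep)
  ids <- c("hog", "lbp", if (length(deep)) paste0("deep:", deep))
  defaults <- stats::setNames(
    c(400L, 500L, rep(400L, length(deep))), ids)
  red <- as.list(defaults)
  for (nm in names(reduce)) {
    if (!nm %in% ids) stopf("reduce refers to unknown block '%s'", nm)
    red[[nm]] <- as.integer(reduce[[nm]])
  }
  for (nm in ids) if (!is_count(red[[nm]]))
    stopf("block '%s' needs a positive reduction size", nm)
  criterion <- match.arg(criterion, c("MID", "MIQ"))
  denominator <- match.arg(denominator, c("retrieved", "database"))
  for (m in metrics) metric_spec(m)
  structure(list(working_size = as.integer(working_size), hog = hog,
                 lbp = lbp, deep = deep, reduce = red, criterion = criterion,
                 bins = as.integer(bins), metrics = as.character(metrics),
                 k = as.integer(k), denominator = denominator,
                 phantom = phantom, seed = as.integer(seed)),
            class = "pipeline_config")
}

# plain-list <-> config conversions shared by the YAML config file and the
# index JSON sidecar
config_to_list <- function(cfg) {
  list(working_size = cfg$working_size,
       hog = unclass(cfg$hog), lbp = unclass(cfg$lbp),
       deep = as.list(cfg$deep), reduce = cfg$reduce,
       criterion = cfg$criterion, bins = cfg$bins,
       metrics = as.list(cfg$metrics), k = cfg$k,
       denominator = cfg$denominator,
       phantom = unclass(cfg$phantom), seed = cfg$seed)
}

take_formals <- function(fn, args)
  args[intersect(names(args), names(formals(fn)))]

list_to_config <- function(l) {
  pipeline_config(
    working_size = l$working_size,
    hog = do.call(hog_params, take_formals(hog_params, l$hog)),
    lbp = do.call(lbp_params, take_formals(lbp_params, l$lbp)),
    deep = as.character(unlist(l$deep)),
    reduce = l$reduce,
    criterion = l$criterion, bins = l$bins,
    metrics = as.character(unlist(l$metrics)), k = l$k,
    denominator = l$denominator,
    phantom = do.call(phantom_config, l$phantom),
    seed = l$seed)
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization is lossless: `read_config(write_config(cfg, f))` returns a
#' configuration identical to `cfg`.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(config_to_list(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  list_to_config(yaml::read_yaml(path))
}

resolve_extractors <- function(cfg, extractors = NULL) {
  if (is.null(extractors))
    extractors <- lapply(cfg$deep, builtin_extractor)
  for (e in extractors) if (!inherits(e, "deep_extractor"))
    stopf("extractors must be deep_extractor objects")
  nms <- vapply(extractors, function(e) e$name, character(1))
  if (!identical(sort(nms), sort(cfg$deep)))
    stopf("extractors (%s) do not match config deep plugins (%s)",
          paste(nms, collapse = ","), paste(cfg$deep, collapse = ","))
  extractors[match(cfg$deep, nms)]
}

#' Raw descriptor vectors of one image under a pipeline configuration
#'
#' @param image a [gray_image()] at the configured working size.
#' @param cfg a [pipeline_config()].
#' @param extractors optional list of [deep_extractor()]s overriding the
#'   built-ins named in `cfg$deep`.
#' @return named list of raw feature vectors keyed by descriptor id, suitable
#'   for [project_query()].
#' @export
query_image_features <- function(image, cfg, extractors = NULL) {
  extractors <- resolve_extractors(cfg, extractors)
  out <- list(hog = hog_features(image, cfg$hog),
              lbp = lbp_features(image, cfg$lbp))
  for (e in extractors)
    out[[paste0("deep:", e$name)]] <- deep_features(image, e)
  out
}

extract_blocks <- function(dataset, cfg, extractors = NULL) {
  extractors <- resolve_extractors(cfg, extractors)
  n <- length(dataset$images)
  one <- function(fn) t(vapply(dataset$images, fn,
                               numeric(length(fn(dataset$images[[1L]])))))
  blocks <- list()
  blocks$hog <- feature_block(one(function(im) hog_features(im, cfg$hog)),
                              "hog", dataset$ids, dataset$labels)
  log_msg(sprintf("extracted hog: %d x %d", n, ncol(blocks$hog$matrix)))
  blocks$lbp <- feature_block(one(function(im) lbp_features(im, cfg$lbp)),
                              "lbp", dataset$ids, dataset$labels)
  log_msg(sprintf("extracted lbp: %d x %d", n, ncol(blocks$lbp$matrix)))
  for (e in extractors) {
    id <- paste0("deep:", e$name)
    blocks[[id]] <- feature_block(one(function(im) deep_features(im, e)),
                                  id, dataset$ids, dataset$labels)
    log_msg(sprintf("extracted %s: %d x %d", id, n,
                    ncol(blocks[[id]]$matrix)))
  }
  blocks
}

#' Build the fused retrieval index from a labeled dataset
#'
#' Extracts every configured descriptor block, fits mRMR selection per block
#' on the labeled database, reduces each block to its configured size, and
#' fuses the reduced blocks into the normalized index. Selection is fitted
#' once here and frozen; queries reuse it via [project_query()].
#'
#' @param dataset a [labeled_dataset()].
#' @param cfg a [pipeline_config()].
#' @param extractors optional list of [deep_extractor()]s (see
#'   [query_image_features()]).
#' @return A [fuse()]d index carrying `cfg` as `$config`.
#' @export
build_index <- function(dataset, cfg = pipeline_config(), extractors = NULL) {
  blocks <- extract_blocks(dataset, cfg, extractors)
  reduced <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    kb <- cfg$reduce[[b$descriptor_id]]
    if (kb > ncol(b$matrix))
      stopf("block '%s' has %d features, cannot select %d",
            b$descriptor_id, ncol(b$matrix), kb)
    sel <- mrmr_select(b, kb, cfg$criterion, cfg$bins)
    reduced[[i]] <- reduce_block(b, sel)
    log_msg(sprintf("mrmr %s: %d -> %d (%s, %d bins)", b$descriptor_id,
                    ncol(b$matrix), kb, cfg$criterion, cfg$bins))
  }
  index <- fuse(reduced)
  index$config <- cfg
  log_msg(sprintf("fused index: %d x %d", nrow(index$matrix),
                  ncol(index$matrix)))
  index
}
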