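#' Read a single-channel fluorescence image
#'
#' Reads a 16-bit (or 8-bit) grayscale TIFF or PNG into a numeric matrix
#' in ADU, rows = y and columns = x, together with the recorded bit
#' depth. A multi-page TIFF yields its first page with a warning; RGB
#' input is refused with instructions to extract one channel first.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return list with `image` (numeric matrix, ADU), `bit_depth`, `path`.
#' @export
readChannelImage <- function(path) {
    stopIfNot(file.exists(path), paste("file not found:", path))
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                          error = function(e)
                              stop("cannot read TIFF ", path, ": ",
                                   conditionMessage(e)))
        if (length(pages) > 1L)
            warning("multi-page TIFF: using the first page of ", path)
        img <- pages[[1L]]
    } else if (ext == "png") {
        img <- tryCatch(png::readPNG(path),
                        error = function(e)
                            stop("cannot read PNG ", path, ": ",
                                 conditionMessage(e)))
        ## png gives [0,1]; rescale to the integer ADU range
        bits <- if (max(img) <= 1) 16L else 8L
        img <- round(img * 65535)
    }
    else stop("unsupported image format: ", ext)
    if (length(dim(img)) == 3L) {
        if (dim(img)[3L] == 1L) img <- img[, , 1L]
        else stop("RGB/multi-channel input: extract a single channel ",
                  "before calling readChannelImage()")
    }
    mx <- max(img)
    bitDepth <- if (mx > 255) 16L else 8L
    list(image = img, bit_depth = bitDepth, path = path)
}

#' Write a rendered scene to disk
#'
#' Writes the two channels as single-channel 16-bit TIFFs (`<stem>_ref.tif`,
#' `<stem>_sig.tif`), the ground truth as CSV
#' (`id,center_x_px,center_y_px,diameter_um,n_entities,is_positive`), and
#' the scene parameters as a JSON sidecar. Written images round-trip
#' bit-identically through [readChannelImage()].
#'
#' @param imgs list with `ref` and `sig` matrices (ADU), as returned by
#'   [renderTwoChannel()].
#' @param gt the matching [GroundTruth-class] object.
#' @param params the [SceneParams-class] used.
#' @param stem output path stem (directories are created).
#' @return character vector of the four paths written.
#' @export
writeSceneImages <- function(imgs, gt, params, stem) {
    dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
    paths <- c(ref = paste0(stem, "_ref.tif"),
               sig = paste0(stem, "_sig.tif"),
               truth = paste0(stem, "_truth.csv"),
               params = paste0(stem, "_params.json"))
    for (ch in c("ref", "sig"))
        tiff::writeTIFF(round(imgs[[ch]]) / 65535, paths[[ch]],
                        bits.per.sample = 16L)
    df <- compartments(gt)
    out <- data.frame(id = df$id, center_x_px = df$center_x,
                      center_y_px = df$center_y,
                      diameter_um = df$diameter_um,
                      n_entities = df$n_entities,
                      is_positive = df$is_positive)
    utils::write.csv(out, paths[["truth"]], row.names = FALSE)
    jsonlite::write_json(sceneParamsAsList(params), paths[["params"]],
                         auto_unbox = TRUE, digits = NA)
    paths
}

#' @rdname writeSceneImages
#' @param object a [SceneParams-class] object.
#' @export
sceneParamsAsList <- function(object) {
    sl <- slotNames(object)
    stats::setNames(lapply(sl, function(s) slot(object, s)), sl)
}

#' Write a per-compartment table as CSV
#'
#' Columns: `id,center_x_px,center_y_px,diameter_um,circularity,mean_ref,
#' mean_sig,ratio,touches_border,n_cells` (plus `is_positive` when calls
#' are present). An empty table writes the header only.
#'
#' @param comps detection table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCompartmentTable <- function(comps, path) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    cols <- data.frame(id = comps$id,
                       center_x_px = comps$center_x,
                       center_y_px = comps$center_y,
                       diameter_um = comps$diameter_um,
                       circularity = comps$circularity,
                       mean_ref = comps$mean_ref,
                       mean_sig = comps$mean_sig,
                       ratio = comps$ratio,
                       touches_border = comps$touches_border,
                       n_cells = if ("n_cells" %in% names(comps))
                           comps$n_cells
                       else rep(NA_integer_, nrow(comps)))
    if ("is_positive" %in% names(comps))
        cols$is_positive <- comps$is_positive
    utils::write.csv(cols, path, row.names = FALSE)
    invisible(path)
}

## Generic S4 -> plain list (for JSON serialisation).
.s4ToList <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    sl <- slotNames(x)
    out <- lapply(sl, function(s) {
        v <- slot(x, s)
        if (isS4(v)) .s4ToList(v) else v
    })
    stats::setNames(out, sl)
}

#' Write an experiment report to a directory
#'
#' Persists a [runExperiment()] report: the compartment table and ground
#' truth as CSV, and a JSON report referencing them by path, carrying the
#' config echo (including the seed) so the run is reproducible.
#'
#' @param report list from [runExperiment()].
#' @param outDir output directory (created if needed).
#' @return named character vector of paths written.
#' @export
writeTables <- function(report, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(compartments = file.path(outDir, "compartments.csv"),
               ground_truth = file.path(outDir, "ground_truth.csv"),
               report = file.path(outDir, "report.json"))
    writeCompartmentTable(report$compartments, paths[["compartments"]])
    gtdf <- compartments(report$ground_truth)
    utils::write.csv(gtdf, paths[["ground_truth"]], row.names = FALSE)
    js <- list(
        config = report$config_echo,
        size_stats = .s4ToList(report$size_stats),
        threshold_fit = if (!is.null(report$threshold_fit))
            .s4ToList(report$threshold_fit) else NULL,
        call_summary = .s4ToList(report$call_summary),
        digital_result = .s4ToList(report$digital_result),
        tables = list(compartments = unname(paths[["compartments"]]),
                      ground_truth = unname(paths[["ground_truth"]])),
        written_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    jsonlite::write_json(js, paths[["report"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths
}
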