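# Annotation I/O. YOLO-txt (LabelImg-compatible) is the primary dialect:
# one `class cx cy w h` line per object, all normalized to [0, 1], with an
# optional trailing confidence column for predictions. COCO-JSON
# (images/annotations/categories, bbox = [x, y, w, h] absolute pixels) is
# the secondary dialect for interoperability. Normalized YOLO centers are
# converted to the package's 0-based half-open pixel boxes here and
# nowhere else.

.defaultClassMap <- c("tooth", "wsl")  # class id 0, 1

#' Read a YOLO-txt label file
#'
#' Converts normalized center boxes to absolute half-open pixel boxes.
#' Boxes reaching outside the frame are clipped; the number of clipped
#' boxes is attached as attribute `clipped` (with a warning). Malformed
#' lines raise an error naming the line number.
#'
#' @param path label file path.
#' @param width,height image dimensions in pixels (YOLO boxes are
#'   normalized, so dimensions must be known).
#' @param classMap character vector mapping 0-based class ids to labels.
#' @return box data.frame with `label` and, when present in the file,
#'   `confidence`.
#' @examples
#' f <- tempfile(); writeLines("1 0.5 0.5 0.2 0.2", f)
#' readYoloLabels(f, 1000, 1000)  # box [400, 400, 600, 600], label wsl
#' @export
readYoloLabels <- function(path, width, height,
                           classMap = .defaultClassMap) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- wslBoxes(numeric(), numeric(), numeric(), numeric(),
                    label = character())
  if (length(lines) == 0L) return(structure(empty, clipped = 0L))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (!(length(f) %in% c(5L, 6L)) || anyNA(v))
      stop("malformed YOLO label line ", i, " in ", path, call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  cls <- as.integer(m[, 1])
  out <- data.frame(xmin = (m[, 2] - m[, 4] / 2) * width,
                    ymin = (m[, 3] - m[, 5] / 2) * height,
                    xmax = (m[, 2] + m[, 4] / 2) * width,
                    ymax = (m[, 3] + m[, 5] / 2) * height,
                    label = ifelse(cls < length(classMap),
                                   classMap[cls + 1L], as.character(cls)))
  if (ncol(m) == 6L) out$confidence <- m[, 6]
  clipped <- sum(out$xmin < 0 | out$ymin < 0 |
                 out$xmax > width | out$ymax > height)
  if (clipped > 0) {
    warning(clipped, " box(es) clipped to image bounds in ", path,
            call. = FALSE)
    out$xmin <- pmax(out$xmin, 0); out$ymin <- pmax(out$ymin, 0)
    out$xmax <- pmin(out$xmax, width); out$ymax <- pmin(out$ymax, height)
  }
  validateBoxes(out)
  structure(out, clipped = as.integer(clipped))
}

#' Write a YOLO-txt label file
#'
#' Normalized center format at 6 decimals; a `confidence` column, if
#' present, is appended as the trailing sixth field (the widely used
#' prediction dialect).
#'
#' @param boxes box data.frame with a `label` column.
#' @param path output path.
#' @param width,height image dimensions in pixels.
#' @param classMap character vector mapping 0-based class ids to labels.
#' @return `path`, invisibly.
#' @export
writeYoloLabels <- function(boxes, path, width, height,
                            classMap = .defaultClassMap) {
  if (nrow(boxes) == 0L) { writeLines(character(), path); return(invisible(path)) }
  cls <- match(boxes$label, classMap) - 1L
  if (anyNA(cls)) stop("label(s) not in classMap: ",
                       paste(setdiff(boxes$label, classMap), collapse = ", "))
  cx <- (boxes$xmin + boxes$xmax) / 2 / width
  cy <- (boxes$ymin + boxes$ymax) / 2 / height
  w <- (boxes$xmax - boxes$xmin) / width
  h <- (boxes$ymax - boxes$ymin) / height
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h)
  if (!is.null(boxes$confidence))
    lines <- sprintf("%s %.6f", lines, boxes$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' Write dataset annotations (and optionally detections) as COCO-JSON
#'
#' Ground truths go to the standard `images`/`annotations`/`categories`
#' schema; detections, when given, to a parallel COCO results array in the
#' same file under `detections`. Id assignment is deterministic (file
#' order).
#'
#' @param records list of [ImageRecord-class] objects.
#' @param path output path.
#' @param detections optional list of per-image detection data.frames
#'   (same order as `records`).
#' @param classMap character vector mapping 0-based class ids to labels.
#' @return `path`, invisibly.
#' @export
writeCoco <- function(records, path, detections = NULL,
                      classMap = .defaultClassMap) {
  images <- lapply(seq_along(records), function(i) {
    d <- imageDims(records[[i]])
    list(id = i, file_name = paste0(imageId(records[[i]]), ".png"),
         width = unname(d["width"]), height = unname(d["height"]))
  })
  categories <- lapply(seq_along(classMap), function(k)
    list(id = k, name = classMap[k]))
  annId <- 0L
  anns <- list()
  for (i in seq_along(records)) {
    ann <- annotations(records[[i]])
    for (j in seq_len(nrow(ann))) {
      annId <- annId + 1L
      anns[[annId]] <- list(
        id = annId, image_id = i,
        category_id = match(ann$label[j], classMap),
        bbox = c(ann$xmin[j], ann$ymin[j],
                 ann$xmax[j] - ann$xmin[j], ann$ymax[j] - ann$ymin[j]),
        area = (ann$xmax[j] - ann$xmin[j]) * (ann$ymax[j] - ann$ymin[j]),
        iscrowd = 0)
    }
  }
  doc <- list(images = images, annotations = anns, categories = categories)
  if (!is.null(detections)) {
    dets <- list()
    for (i in seq_along(detections)) {
      d <- detections[[i]]
      if (is.null(d)) next
      for (j in seq_len(nrow(d)))
        dets[[length(dets) + 1L]] <- list(
          image_id = i, category_id = match(d$label[j], classMap),
          bbox = c(d$xmin[j], d$ymin[j],
                   d$xmax[j] - d$xmin[j], d$ymax[j] - d$ymin[j]),
          score = d$confidence[j])
    }
    doc$detections <- dets
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-JSON file written by [writeCoco()]
#'
#' @param path input path.
#' @return list with `records` (list of [ImageRecord-class]) and
#'   `detections` (list of per-image detection data.frames, or `NULL`).
#' @export
readCoco <- function(path) {
  doc <- jsonlite::read_json(path)
  classMap <- vapply(doc$categories, function(c) c$name, "")
  catIds <- vapply(doc$categories, function(c) c$id, 1)
  byImage <- split(doc$annotations,
                   vapply(doc$annotations, function(a) a$image_id, 1))
  records <- lapply(doc$images, function(im) {
    anns <- byImage[[as.character(im$id)]]
    boxes <- if (is.null(anns))
      wslBoxes(numeric(), numeric(), numeric(), numeric(), label = character())
    else do.call(rbind, lapply(anns, function(a) {
      b <- unlist(a$bbox)
      data.frame(xmin = b[1], ymin = b[2], xmax = b[1] + b[3],
                 ymax = b[2] + b[4],
                 label = classMap[match(a$category_id, catIds)])
    }))
    ImageRecord(sub("\\.[a-zA-Z]+$", "", im$file_name),
                im$width, im$height, boxes)
  })
  detections <- NULL
  if (!is.null(doc$detections)) {
    detByImage <- split(doc$detections,
                        vapply(doc$detections, function(a) a$image_id, 1))
    detections <- lapply(seq_along(doc$images), function(i) {
      ds <- detByImage[[as.character(i)]]
      if (is.null(ds))
        return(wslBoxes(numeric(), numeric(), numeric(), numeric(),
                        label = character(), confidence = numeric()))
      do.call(rbind, lapply(ds, function(a) {
        b <- unlist(a$bbox)
        data.frame(xmin = b[1], ymin = b[2], xmax = b[1] + b[3],
                   ymax = b[2] + b[4],
                   label = classMap[match(a$category_id, catIds)],
                   confidence = a$score)
      }))
    })
  }
  list(records = records, detections = detections)
}

#' Seeded random dataset split
#'
#' Shuffles the records with the given seed and partitions them into
#' train/validation/holdout by the largest-remainder rule: each group gets
#' the floor of its quota and the leftover items go to the groups with the
#' largest fractional remainders (ties to the earlier group). Integer
#' `fractions` are taken as exact requested counts. The default fractions
#' follow the emulated study's 457/130/66 split of 653 images
#' (0.70 / 0.199 / 0.101).
#'
#' @param records list (or vector) of items to split.
#' @param fractions three non-negative numbers: proportions summing to ~1,
#'   or integer counts summing to `length(records)`.
#' @param seed shuffle seed.
#' @return named list `train`, `validation`, `holdout`; disjoint,
#'   exhaustive.
#' @export
splitDataset <- function(records, fractions = c(train = 0.70,
                                                validation = 0.199,
                                                holdout = 0.101),
                         seed = 1L) {
  n <- length(records)
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (all(fractions == round(fractions)) && sum(fractions) == n) {
    counts <- as.integer(fractions)
  } else {
    quota <- fractions / sum(fractions) * n
    counts <- floor(quota)
    left <- n - sum(counts)
    if (left > 0) {
      extra <- order(-(quota - counts))[seq_len(left)]
      counts[extra] <- counts[extra] + 1L
    }
    counts <- as.integer(counts)
  }
  idx <- withLocalSeed(seed, sample.int(n))
  bounds <- cumsum(counts)
  pick <- function(from, to) if (to < from) records[integer()] else
    records[idx[from:to]]
  list(train = pick(1, bounds[1]),
       validation = pick(bounds[1] + 1, bounds[2]),
       holdout = pick(bounds[2] + 1, bounds[3]))
}

#' Read a YAML pipeline configuration file
#'
#' Keys under `pipeline:` override [pipelineConfig()] defaults; keys under
#' `generator:` override [generatorConfig()] defaults; `detector.tooth`
#' and `detector.wsl` hold backend spec strings for [detectorFromSpec()].
#'
#' @param path YAML file path.
#' @return list with `pipeline`, `generator`, `detectors`.
#' @export
readConfigFile <- function(path) {
  y <- yaml::read_yaml(path)
  pipe <- do.call(pipelineConfig, as.list(y$pipeline))
  gen <- do.call(generatorConfig, as.list(y$generator))
  detectors <- lapply(y$detector, function(spec) detectorFromSpec(spec))
  list(pipeline = pipe, generator = gen, detectors = detectors)
}
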