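# COCO-style dataset I/O: PNG frames + a JSON annotation file with a
# single category "free_fluid" (id 1). Boxes are stored as
# (x, y, width, height); in memory they are half-open corner boxes
# (x1, y1, x2, y2). Target-free frames have an image record and no
# annotation records. Image paths are relative to the JSON file.

#' Write a dataset as COCO-style JSON + PNG images
#'
#' @param ds a `phantom_dataset` (or any list of
#'   `list(image, boxes, is_empty)` frames).
#' @param dir output directory (created if needed).
#' @param json_name annotation file name.
#' @return the path of the JSON file, invisibly.
#' @export
write_coco <- function(ds, dir, json_name = "annotations.json") {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  images <- list(); anns <- list(); aid <- 0L
  for (i in seq_along(ds)) {
    s <- ds[[i]]
    fn <- sprintf("images/%06d.png", i)
    png::writePNG(s$image / 255, file.path(dir, fn))
    images[[i]] <- list(id = i, file_name = fn,
                        height = nrow(s$image), width = ncol(s$image))
    if (nrow(s$boxes) > 0) {
      for (bi in seq_len(nrow(s$boxes))) {
        b <- s$boxes[bi, ]
        aid <- aid + 1L
        anns[[aid]] <- list(id = aid, image_id = i, category_id = 1L,
                            bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
                            area = (b[3] - b[1]) * (b[4] - b[2]),
                            iscrowd = 0L)
      }
    }
  }
  obj <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "free_fluid")))
  path <- file.path(dir, json_name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style dataset
#'
#' @param json_path path to the annotation JSON.
#' @return a list of annotated frames (`image`, `boxes`, `is_empty`).
#' @export
read_coco <- function(json_path) {
  if (!file.exists(json_path)) stop("no such annotation file: ", json_path)
  obj <- jsonlite::read_json(json_path)
  if (is.null(obj$images)) stop("malformed COCO JSON: no 'images' field")
  root <- dirname(json_path)
  by_img <- list()
  for (a in obj$annotations) {
    bb <- as.numeric(unlist(a$bbox))
    if (bb[3] <= 0 || bb[4] <= 0)
      stop("non-positive box dimensions in annotation ", a$id)
    key <- as.character(a$image_id)
    by_img[[key]] <- rbind(by_img[[key]],
                           c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]))
  }
  ds <- lapply(obj$images, function(im) {
    f <- file.path(root, im$file_name)
    if (!file.exists(f)) stop("missing image file: ", im$file_name)
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    boxes <- by_img[[as.character(im$id)]]
    if (is.null(boxes)) boxes <- matrix(numeric(0), 0, 4)
    list(image = round(px * 255), boxes = boxes,
         is_empty = nrow(boxes) == 0L, id = im$id)
  })
  class(ds) <- "phantom_dataset"
  ds
}

#' Export detections as COCO results JSON
#'
#' @param dets per-image list of detection data.frames (from
#'   [decode_detections()] after NMS).
#' @param image_ids image id per entry.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(dets, image_ids, path) {
  res <- list(); k <- 0L
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    if (nrow(d) == 0) next
    for (j in seq_len(nrow(d))) {
      k <- k + 1L
      res[[k]] <- list(image_id = image_ids[i], category_id = 1L,
                       bbox = c(d$x1[j], d$y1[j], d$x2[j] - d$x1[j],
                                d$y2[j] - d$y1[j]),
                       score = d$score[j])
    }
  }
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
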