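# Minimal 5x7 bitmap font for the synthetic sheet generator. Rendering only
# needs to *look* like printed text to the line-contrast detector (the
# fixture OCR engine reads the ground-truth sidecar, not pixels), so the
# glyph set is schematic: lowercase letters reuse the uppercase shapes and
# unmapped characters render as a filled box.

FONT_5X7 <- local({
  g <- list(
    "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
    "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
    "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
    "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
    "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
    "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    "I" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
    "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
    "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
    "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
    "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
    "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
    "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
    "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
    "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
    "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
    "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
    "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
    "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
    "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
    "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
    "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
    "," = c(".....", ".....", ".....", ".....", ".##..", "..#..", ".#..."),
    "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
    "'" = c("..#..", "..#..", ".....", ".....", ".....", ".....", "....."),
    "\"" = c(".#.#.", ".#.#.", ".....", ".....", ".....", ".....", "....."),
    "°" = c(".##..", "#..#.", ".##..", ".....", ".....", ".....", "....."),
    "/" = c("....#", "....#", "...#.", "..#..", ".#...", "#....", "#...."),
    ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
    ";" = c(".....", ".##..", ".##..", ".....", ".##..", "..#..", ".#..."),
    "(" = c("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#."),
    ")" = c(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#..."),
    " " = c(".....", ".....", ".....", ".....", ".....", ".....", "....."),
    "?" = c(".###.", "#...#", "....#", "..##.", "..#..", ".....", "..#..")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#")) * 1
  })
})

font_glyph <- function(ch) {
  up <- toupper(ch)
  if (!is.null(FONT_5X7[[ch]])) return(FONT_5X7[[ch]])
  if (!is.null(FONT_5X7[[up]])) return(FONT_5X7[[up]])
  FONT_5X7[["?"]]
}

# Render text lines as an ink mask (1 = ink). `scale` is the integer pixel
# size of one font unit; glyph cell is 6x8 units (5x7 glyph + 1 unit gap).
render_text_block <- function(lines, scale = 3) {
  scale <- max(1L, as.integer(scale))
  cell_w <- 6L * scale; cell_h <- 8L * scale
  n_rows <- length(lines)
  n_cols <- max(nchar(lines), 1L)
  block <- matrix(0, n_rows * cell_h, n_cols * cell_w)
  for (li in seq_len(n_rows)) {
    chars <- strsplit(lines[li], "")[[1]]
    for (ci in seq_along(chars)) {
      gl <- font_glyph(chars[ci])
      big <- gl[rep(seq_len(7), each = scale), rep(seq_len(5), each = scale)]
      y0 <- (li - 1L) * cell_h; x0 <- (ci - 1L) * cell_w
      block[(y0 + 1):(y0 + 7L * scale), (x0 + 1):(x0 + 5L * scale)] <- big
    }
  }
  block
}
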