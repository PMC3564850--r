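# Warm up the graphics stack outside any test: the first device open in a
# session can emit a one-off fontconfig initialization warning.
suppressWarnings({
  f <- tempfile(fileext = ".png")
  grDevices::png(f, width = 200, height = 200)
  plot.new()
  grDevices::dev.off()
  unlink(f)
})
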