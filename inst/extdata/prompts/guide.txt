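Extraction guide. Work step by step:
1. Locate the experimental panel(s) you were asked about and decide
   whether each is a microscopy image or a scatter plot.
2. For a scatter plot, read the axis titles and units first, then treat
   every plotted point as one experiment and read its coordinates off
   the axes; use the legend to assign the phase outcome of each marker.
3. For microscopy, treat each image or labelled condition as one
   experiment and take the conditions from the panel labels and caption.
4. Search the accompanying text for conditions not shown in the figure,
   such as buffer pH, temperature, or a fixed concentration stated in
   the methods.
5. Record the phase outcome exactly as evidenced; if a condition is not
   stated anywhere, leave it empty rather than guessing.
6. Re-check that the number of entries equals the number of distinct
   experimental conditions shown.
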