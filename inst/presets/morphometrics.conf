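# Morphometrics delimited export preset. 1-based coordinates.
preset = morphometrics
base = 1
cell_id = cellID
spot_id = cellID
frame_id = frame
x = Xcont
y = Ycont
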