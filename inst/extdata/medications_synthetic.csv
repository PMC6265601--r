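medication,category
oxycodone,opioids
morphine,opioids
tramadol,opioids
amitriptyline,tricyclics
nortriptyline,tricyclics
gabapentin,anticonvulsants
pregabalin,anticonvulsants
nabilone,cannabinoids
duloxetine,snris
venlafaxine,snris
ibuprofen,
acetaminophen,
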