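condition,category
fibromyalgia,fibromyalgia
migraine,headaches
tension headache,headaches
lower back pain,back pain
sciatica,back pain
osteoarthritis,arthritis
rheumatoid arthritis,arthritis
depression,depression-anxiety
generalized anxiety disorder,depression-anxiety
neck strain,
carpal tunnel syndrome,
endometriosis,
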