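# Toy duplex model for tests: each stacked WC pair -2, any stack
# involving a wobble pair -1, loops forbidden (max_span 0), no
# initiation, temperature-invariant.
# type	context	dg_ref	dh
stack	AU/AU	-2.00	-2.00
stack	AU/CG	-2.00	-2.00
stack	AU/GC	-2.00	-2.00
stack	AU/GU	-1.00	-1.00
stack	AU/UA	-2.00	-2.00
stack	AU/UG	-1.00	-1.00
stack	CG/AU	-2.00	-2.00
stack	CG/CG	-2.00	-2.00
stack	CG/GC	-2.00	-2.00
stack	CG/GU	-1.00	-1.00
stack	CG/UA	-2.00	-2.00
stack	CG/UG	-1.00	-1.00
stack	GC/AU	-2.00	-2.00
stack	GC/CG	-2.00	-2.00
stack	GC/GC	-2.00	-2.00
stack	GC/GU	-1.00	-1.00
stack	GC/UA	-2.00	-2.00
stack	GC/UG	-1.00	-1.00
stack	GU/AU	-1.00	-1.00
stack	GU/CG	-1.00	-1.00
stack	GU/GC	-1.00	-1.00
stack	GU/GU	-1.00	-1.00
stack	GU/UA	-1.00	-1.00
stack	GU/UG	-1.00	-1.00
stack	UA/AU	-2.00	-2.00
stack	UA/CG	-2.00	-2.00
stack	UA/GC	-2.00	-2.00
stack	UA/GU	-1.00	-1.00
stack	UA/UA	-2.00	-2.00
stack	UA/UG	-1.00	-1.00
stack	UG/AU	-1.00	-1.00
stack	UG/CG	-1.00	-1.00
stack	UG/GC	-1.00	-1.00
stack	UG/GU	-1.00	-1.00
stack	UG/UA	-1.00	-1.00
stack	UG/UG	-1.00	-1.00
loop_open	-	0.00	0.00
loop_ext	-	0.00	0.00
max_span	-	0	0
init	-	0.00	0.00
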