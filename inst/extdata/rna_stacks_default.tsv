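# Intermolecular RNA-RNA duplex parameters (kcal/mol).
# Watson-Crick stacks: Turner-style nearest-neighbor dG37/dH;
# wobble stacks generic. Loop/init terms have dh = dg (temperature-
# invariant). Rescaling: dG(T) = dH - T_K*(dH - dG37)/310.15.
# type	context	dg_ref	dh
stack	AU/AU	-0.93	-6.82
stack	AU/CG	-2.24	-11.40
stack	AU/GC	-2.08	-10.48
stack	AU/GU	-1.00	-6.00
stack	AU/UA	-1.10	-9.38
stack	AU/UG	-1.00	-6.00
stack	CG/AU	-2.11	-10.44
stack	CG/CG	-3.26	-13.39
stack	CG/GC	-2.36	-10.64
stack	CG/GU	-1.00	-6.00
stack	CG/UA	-2.08	-10.48
stack	CG/UG	-1.00	-6.00
stack	GC/AU	-2.35	-12.44
stack	GC/CG	-3.42	-14.88
stack	GC/GC	-3.26	-13.39
stack	GC/GU	-1.00	-6.00
stack	GC/UA	-2.24	-11.40
stack	GC/UG	-1.00	-6.00
stack	GU/AU	-1.00	-6.00
stack	GU/CG	-1.00	-6.00
stack	GU/GC	-1.00	-6.00
stack	GU/GU	-1.00	-6.00
stack	GU/UA	-1.00	-6.00
stack	GU/UG	-1.00	-6.00
stack	UA/AU	-1.33	-7.69
stack	UA/CG	-2.35	-12.44
stack	UA/GC	-2.11	-10.44
stack	UA/GU	-1.00	-6.00
stack	UA/UA	-0.93	-6.82
stack	UA/UG	-1.00	-6.00
stack	UG/AU	-1.00	-6.00
stack	UG/CG	-1.00	-6.00
stack	UG/GC	-1.00	-6.00
stack	UG/GU	-1.00	-6.00
stack	UG/UA	-1.00	-6.00
stack	UG/UG	-1.00	-6.00
loop_open	-	5.00	5.00
loop_ext	-	1.50	1.50
max_span	-	4	4
init	-	4.10	4.10
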