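# CIE 1951 scotopic luminous efficiency V'(lambda), 10 nm (+505/507 nm), peak 1 at 507 nm
      380	 0.000589
      390	 0.002209
      400	  0.00929
      410	  0.03484
      420	   0.0966
      430	   0.1998
      440	   0.3281
      450	    0.455
      460	    0.567
      470	    0.676
      480	    0.793
      490	    0.904
      500	    0.982
      505	    0.998
      507	        1
      510	    0.997
      520	    0.935
      530	    0.811
      540	     0.65
      550	    0.481
      560	   0.3288
      570	   0.2076
      580	   0.1212
      590	   0.0655
      600	  0.03315
      610	  0.01593
      620	  0.00737
      630	 0.003335
      640	 0.001497
      650	 0.000677
      660	 0.000313
      670	 0.000148
      680	  7.2e-05
      690	  3.5e-05
      700	  1.8e-05
      710	    9e-06
      720	    5e-06
      730	    3e-06
      740	    1e-06
      750	    1e-06
      760	        0
      770	        0
      780	        0
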