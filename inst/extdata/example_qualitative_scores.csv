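group,day,fiber_color,thick,thin,papillary,mid,deep,horizontal,vertical
laser_treated,5,Yellow,+,+,+,+,_,+,_
laser_treated,10,Red,+,_,+,+,_,+,+
laser_treated,30,Yellow,+,_,+,+,_,+,_
laser_treated,30,Red,+,_,_,+,+,+,_
unilluminated_control,5,Green,_,+,+,_,_,+,_
unilluminated_control,10,Yellow,_,+,+,_,_,+,_
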