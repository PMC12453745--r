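emoji,name
😀,grinning face
😃,smiling face with big eyes
😄,smiling face with smiling eyes
😁,beaming face
😂,face with tears of joy
🙂,slightly smiling face
😉,winking face
😊,smiling face
😍,heart eyes
🥰,smiling face with hearts
😘,face blowing a kiss
😜,winking face with tongue
🤗,hugging face
🤔,thinking face
😐,neutral face
😑,expressionless face
😶,face without mouth
🙄,face with rolling eyes
😏,smirking face
😒,unamused face
😔,pensive face
😕,confused face
🙁,slightly frowning face
☹,frowning face
😖,confounded face
😞,disappointed face
😟,worried face
😢,crying face
😭,loudly crying face
😤,face with steam
😠,angry face
😡,pouting face
🤬,face with symbols on mouth
😨,fearful face
😰,anxious face with sweat
😥,sad but relieved face
😓,downcast face with sweat
😩,weary face
😫,tired face
🥺,pleading face
💔,broken heart
❤,red heart
💙,blue heart
👍,thumbs up
👎,thumbs down
🙏,folded hands
😴,sleeping face
😇,smiling face with halo
🎉,party popper
🌧,cloud with rain
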